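---
title: "Model and methods behind parabd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind parabd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The physical model

`parabd` simulates depolymerization-driven chromosome translocation by the
bacterial ParABS machinery with coarse-grained Brownian dynamics.  Two bodies
interact:

* a **ParA bundle**: parallel bead–spring filaments along the x axis,
  cross-linked laterally, with the pole-proximal ends optionally anchored
  (held fixed) and the free, disassembling tips facing the chromosome;
* a **ParB polymer**: a semi-flexible chain representing the
  ParB–*parS*–*ori* complex, whose central section carries ParA-binding
  sites while the two flanking sections are inert and drag a larger
  effective load (they stand for the bulk chromosome).

ParB binding licenses ATP hydrolysis on the contacted ParA subunits;
hydrolyzed subunits at a filament tip depolymerize and diffuse away.  Because
ParB destroys ParA behind its leading edge more effectively than ahead of it,
a co-moving ParA concentration gradient forms and the polymer translocates up
that gradient — a self-diffusiophoretic mechanism.  The package also
implements the documented failure variants: binding restricted to filament
tips, and disassembly by mid-filament severing.

## Units

Lengths are measured in the subunit diameter `a`, energies in `kT`, and time
in `tau0 = a^2/D0`, where `D0` is the diffusion coefficient of a reference
subunit; the reference drag is then `gamma0 = 1`.  A documentation-level
conversion (`a` = 5 nm; `D0` of order µm²/s for a cytoplasmic protein) maps
results to physical units but is never used in computation.

# Interactions

Only the qualitative contracts of the interactions are fixed by the science;
`parabd` adopts the simplest smooth functional forms that satisfy them.  All
constants below are configuration defaults, chosen once so that filaments are
effectively rigid on bundle scales and bond fluctuations are small compared
with `a`; every one of them is overridable in the configuration.

| interaction | form | default |
|---|---|---|
| excluded volume | WCA (truncated–shifted LJ), contact at `a`, `eps = 1 kT` | — |
| chain bond | harmonic about rest length `a` | `k_bond = 100 kT/a²` |
| bundle crosslink | harmonic about the filament spacing `d0` | `k_crosslink = 50 kT/a²` |
| bending | `k (1 − cos θ)` over consecutive bonds | `k_bend_parA = 50 kT`, ParB flexible (`0`) |
| polarization alignment | `(k/2)(cos θ − cos θ0)²` to each adjacent bond | `k_align = 10 kT`, `θ0 = 90°` |
| helical couplings | `(k/2)(p_i·p_j − cos ψ)²`, nn and nnn | `10 kT`; ParA pitch 60°/120°, ParB 36°/72° |
| ParB–ParA binding | `−eps_b · f(r) · g(p_i·ê) · h(−p_j·ê)` | `eps_b = 6 kT`, `r_b = a`, cutoff `1.5 a` |

The binding potential is separable: a radial bump `f = (1 − s²)²` with
`s = (r − r_b)/(range_b − r_b)` (maximum 1 at `r_b`, smoothly zero at the
cutoff) times bounded Gaussian angular factors in the alignment of each
polarization vector with the inter-subunit axis (widths `w_ang_*`, on the
cosine scale).  The global minimum is therefore exactly `−eps_b`, attained
when the two binding sites face each other along the pair axis.  The
`TIP_NO_PARB_POLAR` / `SIDE_NO_PARB_POLAR` forms drop the ParB factor.

Angular potentials are written harmonic in the *cosine* of the relevant
angle rather than the angle itself: identical minima and curvatures at the
target angles, but smooth where `acos` is singular.  Polarization vectors
exist on ParA and on binding-strip ParB subunits; the inert flanks carry no
binding site, so no orientational potential acts on them.

Chain 1–2 neighbors are excluded from the excluded-volume term (the harmonic
bond governs that distance), the standard bead–spring convention; chain
self-avoidance is preserved by all longer-range pairs.

# Dynamics

First-order Euler–Maruyama integration of overdamped Langevin equations:
positions advance by `F dt/(α γ0)` plus Gaussian noise of variance
`2 kT dt/(α γ0)` per component; polarization vectors rotate by
`T dt/γ_rot` plus rotational noise of variance `2 kT dt/γ_rot` per axis
(as a Rodrigues rotation, so unit length is preserved exactly).  The
per-subunit drag factor is `α = 1` for ParA and binding-strip ParB and
`α = 5` for the inert ParB flanks (the chromosomal load); the rotational
drag defaults to `γ0 a²/3`, the stick-boundary ratio for a sphere of
diameter `a`.

**Time step.** `dt = 1e-3 tau0` by default.  The stiffest harmonic term then
relaxes over ten steps and the rms thermal displacement is `0.045 a`.  Two
guards handle the remaining stiffness: a warning when `k_max·dt/γ0 > 0.5`,
and a per-step displacement cap at `0.25 a` that keeps the update stable
through the steep WCA core during collision transients (capped updates are
counted in the run diagnostics; under default conditions they affect well
below 0.1% of particle updates).  Equilibrium-precision measurements (the
dimer Boltzmann check) use `dt = 1e-4`, where the discretization bias is far
below statistical resolution.

**Noise.** A xoshiro256++ generator with a 128-layer ziggurat normal sampler
is built into the compiled core, so a seed determines the identical
trajectory on every platform, independent of R's RNG state.

# Chemistry

Biochemistry is discretized as per-step Bernoulli conversions with
probability `1 − exp(−k dt)` (the configured rates always satisfy
`k dt ≪ 1`):

* **hydrolysis** (`k_h`): a polymerized ParA-ATP subunit whose strongest
  instantaneous ParB pair energy reaches `eps_threshold` (default
  `0.5 eps_b`) converts irreversibly to ADP;
* **tip depolymerization** (`k_d`): an ADP subunit at a free tip leaves its
  filament and becomes a monomer, keeping only excluded volume ("monomers
  rapidly diffuse away"); anchored terminal subunits never leave;
* **severing** (variant): any interior ADP subunit may cut its filament; the
  severed subunit becomes a monomer, the flanks become separate chains, the
  tip-side fragment is unanchored and keeps binding ParB.

A deliberate design decision: *polymerized* subunits remain binding-eligible
after hydrolysis; a subunit loses its ParB affinity only on
depolymerization.  The alternative (ATP-only stickiness) creates a
non-binding hydrolyzed zone of lifetime `1/k_d` at the disassembling front;
at slow disassembly the ParB polymer then detaches and the standard model
never translocates, contradicting its defining behavior.  Depolymerized
monomers do not rebind and never repolymerize; nucleotide exchange and a
cytosolic ParA pool are out of scope.

# System construction and scenarios

`build_system()` is the synthetic-data generator: hexagonally packed (or
cylindrical) filaments at spacing `d0 = 1.5 a`, 40% of subunits crosslinked
to the same-index subunit of the nearest neighboring filament, polarization
vectors initialized on the configured helix; a self-avoiding random-walk ParB
polymer (100 subunits, central 50 binding, by default) placed one coil
radius before the tip plane and pre-bound by chemistry-off relaxation,
repeated in chunks until a few subunits are actually bound, so that runs
measure translocation rather than capture kinetics.  The adsorption
depth of the bound coil equilibrates much more slowly (a few `10³ tau0`),
and the deepening adds a forward COM drift unrelated to disassembly;
steady-state velocity measurements therefore discard an initial burn-in of
that length before fitting.  The binding energy default (`6 kT`) was fixed
by this equilibrium behavior: several kT stronger and the flexible polymer
wets the bundle — it elongates along the axis and creeps without
disassembly — which is not the coil-like bound state the model describes;
much weaker and attachment is not robust.  Even at the default the bound
polymer is moderately elongated along the bundle axis (anisotropy ~3): an
adhesive flexible chain on a cylindrical bundle trades coil entropy for
contacts.  The stretching trend with disassembly rate sits on top of that
baseline and remains strictly monotone.

Scenario presets (`scenario()`) encode the model variants: `standard`
(side-binding, tip-only disassembly), `tip_binding` (`θ0 = 180°` points tip
polarizations outward and eligibility is restricted to tips), `severing`,
`weak_binding`, `fast_disassembly`, `unanchored`, `tube`, `sparse_bundle`
(4× spacing), `force_velocity`, and the sweep presets (`drag_sweep`,
`length_sweep`, `binding_strip_sweep`, `stiff_parb`, `density_sweep`).  The
number of filaments per bundle defaults to 7 (swept in `density_sweep`).

# Observables

Velocity is the least-squares slope of the ParB COM x series with a block
bootstrap error.  The gyration anisotropy is `⟨Rg_x²⟩/⟨Rg_y²⟩` of the ParB
polymer (1 for an isotropic coil).  Penetration depth is
`max(0, x_q90(bound ParB) − x̄_tips)` — the 90th percentile is used instead
of the maximum for noise robustness.  "Bound" means a pair energy of at
least `0.5 kT` in magnitude.  Detachment is scored against the *anchored bundle*: from the first attached
sample onward, the count of ParB subunits bound to anchored-filament ParA
must stay zero and the ParB COM farther than `range_b + a` from every
anchored-filament subunit for a sustained dwell (a few `tau0`), which
avoids counting instantaneous unbinding fluctuations.  Severed free
fragments do not count as attachment (riding a fragment raft away from the
bundle is the severing failure mode), and neither does an anchored chain
reduced to its single immortal terminal subunit (a filament requires at
least one bond; counting bare stubs would make detachment impossible in any
fully disassembled run).  "Crossing" means a COM advance of one initial
bundle length.  Concentration
profiles are histograms of polymerized ParA positions relative to the
instantaneous ParB COM, averaged over frames.  Unanchored-bundle speeds are
measured on the fixed set of subunits still polymerized at the window's end,
so depolymerization events do not bias the slope.

# Companion theory

* **Relaxation time** `tau = n_seg γ_seg Rg_x²/kT` — a peripheral segment as
  an entropic spring `kT/Rg_x²` loaded by its internal drag (prefactor
  exposed, default 1).
* **Maximum disassembly rate** `k_max = [1/k_d + λ/(k_h δ)]⁻¹` — the serial
  combination of depolymerization and penetration-limited hydrolysis; linear
  in `k_h` at small rates, saturating at `k_d`; `λ` defaults to `a`.
* **Velocity regimes** in `k_max·tau`: regime I (`< 0.1`), coil intact and
  `v = a·k_max`; regime II (0.1–10), stretched, `a·k_max` is an upper
  bound; regime III (`> 10`), detachment, `v = 0`.  The thresholds stand in
  for the asymptotic conditions and are configurable.
* **Effective potential** for the bound polymer's COM:
  `U_eff(x) = −eps_b N_B Φ(x/Rg_x) − F x` — the error-function overlap
  follows from the approximately Gaussian distribution of ParB subunits
  about their COM (a sharper cutoff was the alternative; the Gaussian cloud
  argument favors `Φ`).
* **Kramers escape**: the standard overdamped two-curvature expression
  `t_esc = 2πγ/√(U''_w |U''_b|) · exp(ΔU/kT)`, with well and barrier located
  by stationary-point analysis of the tilted potential; below `2 kT` the
  formula is flagged as degraded, and past the critical force a
  drift-time fallback is returned with a `no_barrier` flag.
* **Detachment force**: the root of `t_esc(F) = t_trans` by bisection.
* **Unanchored force balance**: `γ_A v_A = −γ_B v_B`, so the speed ratio is
  the inverse drag ratio.

# What the generator does and does not emulate

Runs reproduce the mechanistic behaviors: regime-I velocity `v = a k_D`,
polymer stretching and the anisotropy trend with `k_d`, detachment of the
tip-binding and severing variants, threshold behavior in binding energy and
strip length, the co-moving front-loaded ParA gradient, unanchored
force balance, and survival of far filaments in sparse bundles.  They do not
include hydrodynamic flow, electrostatics, sequence-specific DNA mechanics,
ParA–nucleoid nonspecific binding, repolymerization or nucleotide exchange,
or confinement by the cell wall (anchoring is the only pole effect; an
optional cylindrical restraint exists but is off by default).  Passing tests
therefore validate the model's internal physics and statistics, not
quantitative agreement with in-vivo kinetics.

# Problem sizes used by the tests

The test-suite and acceptance script use scaled-down study systems chosen to
resolve each effect with adequate statistics on a single CPU: the regime-I
law on the 7×30-subunit bundle with a 60-subunit polymer over `10⁴ tau0`
with the first 30% discarded as adsorption burn-in (`k_d = 5·10⁻⁴`, giving
`k_max·tau ≈ 0.09`); failure-mode and threshold
comparisons on 4×12 bundles with 30-subunit polymers at `k_d = 5·10⁻³` over
`600–800 tau0` with 4–8 replicates; the thermostat on 64 free subunits and a
single dimer at refined `dt`; the 1D first-passage oracle on a narrow
tilted well where escape times are short.  Event counts, not run lengths,
limit the precision of rate comparisons, which is why the velocity-law check
carries a 15% tolerance.

# Known limitations

* The Euler–Maruyama collision overshoot makes the excluded-volume core
  effectively slightly softer at `dt = 10⁻³`; contact statistics at better
  than a few percent require the refined step.
* The regime-II/III boundary is diffuse; the package reports its own
  measured boundaries rather than asserting literature values.
* Observables assume a single ParB polymer; multiple polymers per run are
  not supported.
* The displacement cap, while rarely active, formally breaks strict detailed
  balance during deep-overlap transients.
* The slow adsorption-deepening mode adds a forward COM drift whose duration
  varies between realizations; even with a multi-`10³ tau0` burn-in,
  individual regime-I realizations can show a COM velocity tens of percent
  above `a·k_D` when the deepening has not finished.  Front-position
  recession, by contrast, always tracks `a·k_D` exactly.
* Lab-frame velocities of the unanchored bundle/polymer pair are dominated
  by free diffusion of the joint center of drag at desk scales; the force
  balance is resolvable only in drag-weighted (standardized) form.
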
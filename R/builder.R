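#' Geometry specification for the initial system
#'
#' Describes the ParA bundle (parallel filaments along +x, free tips at small
#' x, pole-anchored ends at large x) and the ParB polymer (a semi-flexible
#' chain whose central section carries the ParA-binding sites, flanked by two
#' inert sections with a larger drag factor).
#'
#' @param n_filaments number of ParA filaments (hexagonally packed by
#'   default).
#' @param filament_length subunits per filament.
#' @param arrangement `"PACKED_BUNDLE"` (hexagonal lattice) or `"TUBE"`
#'   (filaments on a ring).
#' @param spacing filament lattice spacing d0 (a); the sparse-bundle variant
#'   uses four times the standard spacing.
#' @param crosslink_fraction fraction of ParA subunits crosslinked to the
#'   same-index subunit of the nearest neighboring filament.
#' @param anchored logical: anchor each filament's pole-side end.
#' @param parb_total_length total ParB polymer length (subunits).
#' @param parb_binding_length length of the central binding strip (subunits,
#'   centered).
#' @param parb_start_offset initial gap between the ParB center of mass and
#'   the bundle free-tip plane (a); `NULL` uses one ideal-coil radius of
#'   gyration of the polymer.
#' @param external_force magnitude (kT/a) of a load pulling each of the two
#'   terminal ParB subunits in -x (force-velocity scenario).
#' @param cell_confinement `NULL`, or a cylinder radius (a) about the x axis.
#' @param alpha_para,alpha_parb,alpha_inert drag factors for ParA subunits,
#'   binding-strip ParB subunits, and inert ParB subunits.
#' @param n_relax_steps pre-run relaxation steps with chemistry off (lets
#'   the ParB polymer equilibrate locally and attach to the bundle tip so
#'   runs measure translocation, not attachment kinetics).
#' @return an object of class `pb_geometry`.
#' @export
geometry_spec <- function(n_filaments = 7, filament_length = 50,
                          arrangement = "PACKED_BUNDLE", spacing = 1.5,
                          crosslink_fraction = 0.4, anchored = TRUE,
                          parb_total_length = 100, parb_binding_length = 50,
                          parb_start_offset = NULL, external_force = 0,
                          cell_confinement = NULL,
                          alpha_para = 1, alpha_parb = 1, alpha_inert = 5,
                          n_relax_steps = 20000) {
  g <- list(n_filaments = n_filaments, filament_length = filament_length,
            arrangement = arrangement, spacing = spacing,
            crosslink_fraction = crosslink_fraction, anchored = isTRUE(anchored),
            parb_total_length = parb_total_length,
            parb_binding_length = parb_binding_length,
            parb_start_offset = parb_start_offset,
            external_force = external_force,
            cell_confinement = cell_confinement,
            alpha_para = alpha_para, alpha_parb = alpha_parb,
            alpha_inert = alpha_inert, n_relax_steps = n_relax_steps)
  validate_geometry(g)
}

validate_geometry <- function(g) {
  if (!g$arrangement %in% c("PACKED_BUNDLE", "TUBE"))
    stop("arrangement must be PACKED_BUNDLE or TUBE (field 'arrangement')")
  if (g$parb_binding_length > g$parb_total_length)
    stop("parb_binding_length must not exceed parb_total_length")
  if (g$crosslink_fraction < 0 || g$crosslink_fraction > 1)
    stop("crosslink_fraction must lie in [0, 1]")
  if (g$spacing < 1)
    stop("spacing must be >= the subunit diameter (field 'spacing')")
  if (g$n_filaments < 1 || g$filament_length < 1)
    stop("need at least one filament of at least one subunit")
  class(g) <- "pb_geometry"
  g
}

# lattice of filament cross-section centers
filament_lattice <- function(n, spacing, arrangement) {
  if (arrangement == "TUBE") {
    if (n == 1) return(matrix(0, 1, 2))
    R <- spacing / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(R * cos(th), R * sin(th)))
  }
  # hexagonal packing: enumerate shells and keep the n innermost sites
  pts <- list(c(0, 0))
  for (q in -4:4) for (r in -4:4) {
    if (q == 0 && r == 0) next
    pts[[length(pts) + 1]] <- spacing * c(q + r / 2, r * sqrt(3) / 2)
  }
  m <- do.call(rbind, pts)
  m <- m[order(rowSums(m^2), atan2(m[, 2], m[, 1])), , drop = FALSE]
  if (n > nrow(m)) stop("too many filaments for the built-in lattice")
  m[seq_len(n), , drop = FALSE]
}

#' Build the ParA filament bundle
#'
#' Parallel filaments along x with free tips at x = 0, pole ends at
#' `x = (L-1) a`; polarization vectors initialized on the configured helix;
#' a random `crosslink_fraction` of subunits crosslinked to the same-index
#' subunit of the nearest neighboring filament.
#'
#' @param spec a [geometry_spec()].
#' @param ff a [ff_params()] object (supplies the helical pitch).
#' @param seed RNG seed (crosslink sampling).
#' @return list with `pos`, `pol`, `chains`, `crosslinks`,
#'   `n_crosslinked_subunits`.
#' @export
build_bundle <- function(spec, ff, seed = 1L) {
  nf <- spec$n_filaments; L <- spec$filament_length
  lat <- filament_lattice(nf, spec$spacing, spec$arrangement)
  N <- nf * L
  pos <- matrix(0, N, 3)
  pol <- matrix(0, N, 3)
  chains <- vector("list", nf)
  for (f in seq_len(nf)) {
    ids <- ((f - 1) * L + 1):(f * L)
    chains[[f]] <- ids
    pos[ids, 1] <- seq(0, L - 1) * ff$a
    pos[ids, 2] <- lat[f, 1]
    pos[ids, 3] <- lat[f, 2]
    phi <- (seq_len(L) - 1) * ff$psi_nn_parA_deg * pi / 180 +
      2 * pi * (f - 1) / max(1, nf)
    pol[ids, ] <- cbind(0, cos(phi), sin(phi))
  }
  # crosslinks: sampled subunits link to the same-index subunit of the
  # nearest neighboring filament
  xl <- matrix(integer(0), 0, 2)
  n_sel <- round(spec$crosslink_fraction * N)
  if (n_sel > 0 && nf > 1) {
    nearest <- sapply(seq_len(nf), function(f) {
      d <- rowSums((lat - matrix(lat[f, ], nf, 2, byrow = TRUE))^2)
      d[f] <- Inf
      which.min(d)
    })
    withr::with_seed(seed, {
      sel <- sample.int(N, n_sel)
    })
    f_of <- rep(seq_len(nf), each = L)
    k_of <- rep(seq_len(L), nf)
    partner <- (nearest[f_of[sel]] - 1) * L + k_of[sel]
    pr <- cbind(pmin(sel, partner), pmax(sel, partner))
    xl <- unique(pr)
  }
  list(pos = pos, pol = pol, chains = chains, crosslinks = xl,
       n_crosslinked_subunits = if (nrow(xl)) length(unique(as.vector(xl))) else 0L,
       n_selected = n_sel)
}

# grow a self-avoiding random-walk chain of n beads with bond length a,
# avoiding `obstacles` (matrix) at min distance `clearance`
grow_saw <- function(n, a = 1, start = c(0, 0, 0), obstacles = NULL,
                     clearance = 0.9) {
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- start
  i <- 2
  tries <- 0
  while (i <= n) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    cand <- pos[i - 1, ] + a * u
    ok <- TRUE
    if (i > 2) {
      d2 <- rowSums((pos[1:(i - 2), , drop = FALSE] -
                       matrix(cand, i - 2, 3, byrow = TRUE))^2)
      ok <- all(d2 > clearance^2)
    }
    if (ok && !is.null(obstacles) && nrow(obstacles)) {
      d2 <- rowSums((obstacles - matrix(cand, nrow(obstacles), 3, byrow = TRUE))^2)
      ok <- all(d2 > clearance^2)
    }
    if (ok) {
      pos[i, ] <- cand
      i <- i + 1
      tries <- 0
    } else {
      tries <- tries + 1
      if (tries > 500) { # back-track
        i <- max(2, i - 5)
        tries <- 0
      }
    }
  }
  pos
}

#' Build the ParB polymer chain
#'
#' A self-avoiding random-walk conformation with the central
#' `parb_binding_length` subunits labeled `PARB_BIND` and the two flanks
#' `PARB_INERT` (with their larger drag factor).  Polarization vectors start
#' random and anneal under the helical couplings during relaxation.
#'
#' @param spec a [geometry_spec()].
#' @param ff a [ff_params()] object.
#' @param seed RNG seed.
#' @param start growth origin.
#' @param obstacles optional coordinates the walk must avoid.
#' @return list with `pos`, `pol`, `species`, `alpha`.
#' @export
build_parb_polymer <- function(spec, ff, seed = 1L, start = c(0, 0, 0),
                               obstacles = NULL) {
  n <- spec$parb_total_length
  nb <- spec$parb_binding_length
  withr::with_seed(seed, {
    pos <- grow_saw(n, ff$a, start, obstacles)
    pol <- matrix(rnorm(3 * n), n, 3)
  })
  pol <- pol / sqrt(rowSums(pol^2))
  n_flank <- floor((n - nb) / 2)
  species <- rep("PARB_INERT", n)
  if (nb > 0) species[(n_flank + 1):(n_flank + nb)] <- "PARB_BIND"
  alpha <- ifelse(species == "PARB_BIND", spec$alpha_parb, spec$alpha_inert)
  list(pos = pos, pol = pol, species = species, alpha = alpha)
}

#' Assemble and relax the full initial system
#'
#' Builds the bundle and the ParB polymer, places the polymer center of mass
#' `parb_start_offset` before the bundle's free-tip plane on the bundle axis,
#' backs it off until no hard overlaps remain, and relaxes with chemistry
#' disabled so the polymer equilibrates and pre-binds the tip region.
#'
#' @param config a scenario configuration (see [scenario()]).
#' @param seed RNG seed (builder and relaxation noise).
#' @return a [pb_state()] ready for [run_simulation()].
#' @export
build_system <- function(config, seed = 1L) {
  config <- validate_config(config)
  g <- config$geometry; ff <- config$forcefield
  bun <- build_bundle(g, ff, seed = seed)
  offset <- g$parb_start_offset
  if (is.null(offset)) offset <- ff$a * sqrt(g$parb_total_length / 6)
  pb <- build_parb_polymer(g, ff, seed = seed + 1L, obstacles = bun$pos)
  # place ParB center of mass at (-offset, 0, 0), then back off if overlapping
  shift <- c(-offset, 0, 0) - colMeans(pb$pos)
  pb$pos <- pb$pos + matrix(shift, nrow(pb$pos), 3, byrow = TRUE)
  for (k in 1:80) {
    dmin <- min(cross_dist2(pb$pos, bun$pos))
    if (dmin > (0.9 * ff$a)^2) break
    pb$pos[, 1] <- pb$pos[, 1] - 0.5 * ff$a
  }
  nA <- nrow(bun$pos); nB <- nrow(pb$pos)
  state <- pb_state(
    pos = rbind(bun$pos, pb$pos),
    pol = rbind(bun$pol, pb$pol),
    species = c(rep("PARA", nA), pb$species),
    nucleotide = c(rep("ATP", nA), rep("NONE", nB)),
    alpha = c(rep(g$alpha_para, nA), pb$alpha),
    anchored = c(if (g$anchored) {
      a <- rep(FALSE, nA)
      for (ch in bun$chains) a[ch[length(ch)]] <- TRUE
      a
    } else rep(FALSE, nA), rep(FALSE, nB)),
    chains = c(bun$chains, list(nA + seq_len(nB))),
    chain_anchored = c(rep(g$anchored, length(bun$chains)), FALSE),
    crosslinks = bun$crosslinks)
  if (g$n_relax_steps > 0) {
    # pre-bind with chemistry off; extend in chunks until the polymer has
    # actually captured the bundle (a handful of bound subunits), so every
    # production run starts from an attached configuration
    target <- min(max(3, round(0.3 * g$parb_binding_length)),
                  g$parb_binding_length)
    bound_count <- function(s) {
      tf <- total_forces(s, config$forcefield, config$chemistry)
      sum(s$species == "PARB_BIND" & tf$min_pair_energy <= -0.5)
    }
    for (chunk in 1:20) {
      relax <- run_simulation(config, seed = seed + 1L + chunk, state = state,
                              n_steps = g$n_relax_steps, chemistry_on = FALSE,
                              sample_stride = 0L, frame_stride = 0L)
      state <- relax$state
      if (config$forcefield$eps_b <= 0 || bound_count(state) >= target) break
    }
    state$time <- 0
  }
  state
}

cross_dist2 <- function(a, b) {
  # pairwise squared distances, small matrices only
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

.SCENARIOS <- c("standard", "tip_binding", "severing", "weak_binding",
                "fast_disassembly", "drag_sweep", "length_sweep", "unanchored",
                "tube", "sparse_bundle", "force_velocity", "binding_strip_sweep",
                "stiff_parb", "density_sweep")

#' Scenario presets
#'
#' Complete, validated configurations for the model variants and parameter
#' sweeps.  Every preset differs from `"standard"` (side-binding with
#' tip-only disassembly) only in its documented fields.
#'
#' @param name one of `"standard"`, `"tip_binding"`, `"severing"`,
#'   `"weak_binding"`, `"fast_disassembly"`, `"drag_sweep"`,
#'   `"length_sweep"`, `"unanchored"`, `"tube"`, `"sparse_bundle"`,
#'   `"force_velocity"`, `"binding_strip_sweep"`, `"stiff_parb"`,
#'   `"density_sweep"`.
#' @param ... overrides applied on top of the preset, as
#'   `geometry = list(...)`, `forcefield = list(...)`,
#'   `chemistry = list(...)`, `integrator = list(...)`.
#' @return a configuration list with elements `scenario_name`, `geometry`,
#'   `forcefield`, `chemistry`, `integrator`, `output`, `sweep`.
#' @export
scenario <- function(name = "standard", ...) {
  if (!name %in% .SCENARIOS)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(.SCENARIOS, collapse = ", "))
  cfg <- list(scenario_name = name,
              geometry = geometry_spec(),
              forcefield = ff_params(),
              chemistry = chemistry_params(),
              integrator = integrator_params(n_steps = 200000L),
              output = list(sample_stride = 200L, frame_stride = 0L),
              sweep = NULL)
  mod <- switch(
    name,
    standard = list(),
    tip_binding = list(chemistry = list(binding_mode = "TIP_ONLY"),
                       forcefield = list(theta0_deg = 180)),
    severing = list(chemistry = list(disassembly_mode = "SEVERING")),
    weak_binding = list(forcefield = list(eps_b = 2),
                        chemistry = list(eps_threshold = 1)),
    fast_disassembly = list(chemistry = list(k_d = 1e-2)),
    drag_sweep = list(sweep = list(parameter = "geometry.alpha_inert",
                                   values = c(1, 5, 25, 125))),
    length_sweep = list(sweep = list(parameter = "geometry.parb_total_length",
                                     values = c(60, 100, 150))),
    unanchored = list(geometry = list(anchored = FALSE)),
    tube = list(geometry = list(arrangement = "TUBE")),
    sparse_bundle = list(geometry = list(spacing = 6),
                         forcefield = list(d0 = 6)),
    force_velocity = list(sweep = list(parameter = "geometry.external_force",
                                       values = c(0, 1, 2, 4, 8))),
    binding_strip_sweep = list(sweep = list(parameter = "geometry.parb_binding_length",
                                            values = c(6, 12, 25, 50, 76))),
    stiff_parb = list(forcefield = list(k_bend_parB = 50),
                      sweep = list(parameter = "forcefield.k_bend_parB",
                                   values = c(0, 10, 50))),
    density_sweep = list(sweep = list(parameter = "geometry.n_filaments",
                                      values = c(4, 7, 13),
                                      match_diameter = TRUE)))
  cfg <- merge_config(cfg, mod)
  cfg <- merge_config(cfg, list(...))
  validate_config(cfg)
}

merge_config <- function(cfg, mod) {
  for (nm in names(mod)) {
    if (nm %in% c("geometry", "forcefield", "chemistry", "integrator", "output") &&
        is.list(mod[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], mod[[nm]], keep.null = TRUE)
    } else {
      cfg[[nm]] <- mod[[nm]]
    }
  }
  cfg
}

#' Apply one sweep value to a configuration
#'
#' Resolves `config$sweep$parameter` (a `"section.field"` path) to `value`.
#' The density sweep keeps the bundle diameter roughly constant by rescaling
#' the filament spacing with `sqrt(n_ref / n)`.
#'
#' @param config a scenario configuration with a `sweep` entry.
#' @param value one element of `sweep$values`.
#' @return the modified configuration.
#' @export
apply_sweep_value <- function(config, value) {
  sw <- config$sweep
  if (is.null(sw)) stop("configuration has no sweep")
  path <- strsplit(sw$parameter, ".", fixed = TRUE)[[1]]
  config[[path[1]]][[path[2]]] <- value
  if (isTRUE(sw$match_diameter) && path[2] == "n_filaments") {
    base <- config$geometry$spacing
    config$geometry$spacing <- max(1, base * sqrt(7 / value))
    config$forcefield$d0 <- config$geometry$spacing
  }
  config$sweep <- NULL
  validate_config(config)
}
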
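# shared fixtures and oracles for the test suite; everything is generated
# in code with fixed seeds

ff_default <- ff_params()

# rotate unit vector p about axis by angle th (Rodrigues)
rot_about <- function(p, ax, th) {
  ax <- ax / sqrt(sum(ax^2))
  cos(th) * p + sin(th) * c(ax[2] * p[3] - ax[3] * p[2],
                            ax[3] * p[1] - ax[1] * p[3],
                            ax[1] * p[2] - ax[2] * p[1]) +
    (1 - cos(th)) * sum(ax * p) * ax
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# central finite difference of f at x along the k-th coordinate
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# a small bonded ParA filament bundle + ParB chain, hand-assembled (no
# relaxation) for chemistry and force tests
make_tiny_state <- function(n_fil = 2, len = 5, n_parb = 6, n_bind = 4,
                            anchored = TRUE, spacing = 1.5, seed = 7) {
  withr::with_seed(seed, {
    nA <- n_fil * len
    pos <- matrix(0, nA + n_parb, 3)
    pol <- matrix(0, nA + n_parb, 3)
    chains <- list()
    for (f in seq_len(n_fil)) {
      ids <- ((f - 1) * len + 1):(f * len)
      chains[[f]] <- ids
      pos[ids, 1] <- seq(0, len - 1)
      pos[ids, 2] <- (f - 1) * spacing
      phi <- seq_along(ids) * pi / 3
      pol[ids, ] <- cbind(0, cos(phi), sin(phi))
    }
    idsB <- nA + seq_len(n_parb)
    pos[idsB, 1] <- -seq_len(n_parb)
    pos[idsB, 3] <- 0.2 * rnorm(n_parb)
    pol[idsB, ] <- t(replicate(n_parb, rand_unit()))
    chains[[n_fil + 1]] <- idsB
    anch <- rep(FALSE, nA + n_parb)
    if (anchored) for (f in seq_len(n_fil)) anch[chains[[f]][len]] <- TRUE
    n_flank <- floor((n_parb - n_bind) / 2)
    speciesB <- rep("PARB_INERT", n_parb)
    if (n_bind > 0) speciesB[(n_flank + 1):(n_flank + n_bind)] <- "PARB_BIND"
    pb_state(pos = pos, pol = pol,
             species = c(rep("PARA", nA), speciesB),
             nucleotide = c(rep("ATP", nA), rep("NONE", n_parb)),
             alpha = c(rep(1, nA), ifelse(speciesB == "PARB_BIND", 1, 5)),
             anchored = anch,
             chains = chains,
             chain_anchored = c(rep(anchored, n_fil), FALSE),
             crosslinks = matrix(integer(0), 0, 2))
  })
}

# reduced-size scenario configuration used by the heavier tests
small_config <- function(name = "standard", n_fil = 4, len = 15,
                         parb = 40, bind = 20, n_relax = 4000, ...) {
  mods <- list(...)
  geo <- list(n_filaments = n_fil, filament_length = len,
              parb_total_length = parb, parb_binding_length = bind,
              n_relax_steps = n_relax)
  if (!is.null(mods$geometry)) {
    geo <- modifyList(geo, mods$geometry)
    mods$geometry <- NULL
  }
  do.call(scenario, c(list(name, geometry = geo), mods))
}

# memoized expensive runs shared across test files (testthat sources all
# helpers into one session, so this cache persists for the whole suite)
.pb_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pb_test_cache))
    assign(key, force(expr), envir = .pb_test_cache)
  get(key, envir = .pb_test_cache)
}

# the shared regime-I translocation run on the 7x30 bundle with a 60-subunit
# ParB polymer (slow disassembly, k_max*tau < 0.1); reused by the velocity,
# anisotropy, and concentration-gradient tests
regime1_run <- function() {
  cached("regime1", {
    cfg <- scenario("standard",
                    geometry = list(filament_length = 30,
                                    parb_total_length = 60,
                                    parb_binding_length = 30,
                                    n_relax_steps = 20000),
                    chemistry = list(k_d = 5e-4, k_h = 0.05),
                    integrator = list(n_steps = 1e7))
    suppressWarnings(run_simulation(cfg, seed = 42, sample_stride = 2000,
                                    frame_stride = 25000))
  })
}

# free-subunit diffusion check (fluctuation-dissipation), cached
diffusion_measurement <- function(alpha = 1) {
  cached(paste0("diff_a", alpha), {
    n <- 64
    pos <- cbind(seq_len(n) * 100, 0, 0)
    st <- pb_state(pos = pos, pol = matrix(rep(c(0, 0, 1), each = n), n, 3),
                   species = rep("PARA", n), nucleotide = rep("ATP", n),
                   alpha = rep(alpha, n), anchored = rep(FALSE, n),
                   chains = list(), chain_anchored = logical(0),
                   crosslinks = matrix(integer(0), 0, 2), n_para0 = n)
    cfg <- scenario("standard", integrator = list(n_steps = 1e5, dt = 1e-3))
    cfg$chemistry$chemistry_on <- FALSE
    run <- run_simulation(cfg, seed = 31 + alpha, state = st,
                          sample_stride = 1000, track_ids = seq_len(n))
    tr <- run$track
    dt_samp <- diff(run$samples$time[1:2])
    inc2 <- unlist(lapply(seq_len(n), function(k) {
      rowSums(apply(tr[, (3 * k - 2):(3 * k)], 2, diff)^2)
    }))
    mean(inc2) / (6 * dt_samp)
  })
}

# bonded-dimer equilibrium bond-length sample at refined dt, cached
dimer_bond_sample <- function() {
  cached("dimer_ks", {
    dimer <- pb_state(pos = rbind(c(0, 0, 0), c(1, 0, 0)),
                      pol = rbind(c(0, 0, 1), c(0, 0, 1)),
                      species = rep("PARA", 2), nucleotide = rep("ATP", 2),
                      alpha = c(1, 1), anchored = c(FALSE, FALSE),
                      chains = list(1:2), chain_anchored = FALSE,
                      crosslinks = matrix(integer(0), 0, 2))
    cfg <- scenario("standard",
                    forcefield = list(k_align = 0, k_helix_nn = 0,
                                      k_helix_nnn = 0, eps_b = 0),
                    integrator = list(dt = 1e-4, n_steps = 3e7))
    cfg$chemistry$chemistry_on <- FALSE
    run <- run_simulation(cfg, seed = 55, state = dimer, sample_stride = 300,
                          track_ids = 1:2)
    tr <- run$track
    list(r = sqrt((tr[, 1] - tr[, 4])^2 + (tr[, 2] - tr[, 5])^2 +
                    (tr[, 3] - tr[, 6])^2),
         k_bond = cfg$forcefield$k_bond)
  })
}

# Kolmogorov-Smirnov comparison of a dimer bond-length sample against the
# Boltzmann distribution of the implemented dimer energy (harmonic bond;
# chain neighbors are 1-2 excluded from WCA) with the r^2 Jacobian
dimer_ks_test <- function(sample = dimer_bond_sample()) {
  grid <- seq(0.5, 1.6, length.out = 4000)
  w <- grid^2 * exp(-0.5 * sample$k_bond * (grid - 1)^2)
  cdf_tab <- cumsum(w) / sum(w)
  pfun <- function(q) approx(grid, cdf_tab, xout = q, rule = 2)$y
  suppressWarnings(stats::ks.test(sample$r, pfun))
}

# equilibrium run of an isolated (free) ParB polymer, cached
free_polymer_run <- function() {
  cached("free_polymer", {
    spec <- geometry_spec(parb_total_length = 60, parb_binding_length = 30)
    ff <- ff_params(eps_b = 0)
    pb <- build_parb_polymer(spec, ff, seed = 91)
    n <- nrow(pb$pos)
    st <- pb_state(pos = pb$pos, pol = pb$pol, species = pb$species,
                   nucleotide = rep("NONE", n), alpha = pb$alpha,
                   anchored = rep(FALSE, n), chains = list(seq_len(n)),
                   chain_anchored = FALSE,
                   crosslinks = matrix(integer(0), 0, 2), n_para0 = 0L)
    cfg <- scenario("standard", forcefield = list(eps_b = 0),
                    integrator = list(n_steps = 2e6))
    cfg$chemistry$chemistry_on <- FALSE
    # species are ParB only, so the gyration samples describe this polymer
    suppressWarnings(run_simulation(cfg, seed = 92, state = st,
                                    sample_stride = 2000))
  })
}

regime1_stats <- function(run = regime1_run()) {
  s <- run$samples
  burn <- s$time > 0.3 * max(s$time)  # adsorption equilibrates during burn-in
  v <- translocation_velocity(s[burn, ])
  dep <- run$events[run$events$kind == "DEPOLYMERIZATION", ]
  tw <- range(s$time[burn])
  ndep <- sum(dep$time >= tw[1] & dep$time <= tw[2])
  kD <- ndep / run$config$geometry$n_filaments / diff(tw)
  list(v = v$v, v_se = v$se, kD = kD, window = tw, n_events = ndep)
}

# exponential waiting time of a hydrolyzed tip subunit, cached (shared by
# the chemistry unit tests and the acceptance statistics)
tip_lifetime_sample <- function() {
  cached("tip_lifetimes", {
    k_d <- 0.2; dt <- 0.05
    ch <- chemistry_params(k_d = k_d)
    base <- make_tiny_state(n_fil = 1, len = 3, n_parb = 2, n_bind = 2)
    lifetimes <- vapply(seq_len(1000), function(r) {
      st <- base
      st$nucleotide[st$chains[[1]][1]] <- "ADP"
      for (step in 1:2000) {
        outd <- depolymerization_step(st, ch, dt = dt, seed = r * 7000 + step)
        if (nrow(outd$events)) return(step * dt)
        st <- outd$state
      }
      NA_real_
    }, numeric(1))
    list(lifetimes = lifetimes, expected = dt / (1 - exp(-k_d * dt)))
  })
}
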
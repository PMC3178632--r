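# observable estimators against planted (synthetic) signals

synth_samples <- function(n = 200, v = 0, noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    t <- seq(1, n)
    data.frame(time = t, parb_x = v * t + rnorm(n, 0, noise),
               parb_y = 0, parb_z = 0,
               g_xx = 1, g_yy = 1, g_zz = 1, g_xy = 0, g_xz = 0, g_yz = 0,
               n_bound = 5, n_bound_anchored = 5, delta = 1, tip_x = 0,
               n_poly = 10, n_filaments = 2,
               dmin_com = 1, cum_hydrolysis = 0, cum_depoly = 0, cum_sever = 0)
  })
}

test_that("translocation velocity recovers planted slopes and rejects tiny windows", {
  s0 <- synth_samples(v = 0)
  v0 <- translocation_velocity(s0)
  expect_lt(abs(v0$v), 3 * v0$se + 1e-4)
  s3 <- synth_samples(v = 0.3, noise = 0.5, seed = 2)
  v3 <- translocation_velocity(s3)
  expect_lt(abs(v3$v - 0.3), 3 * v3$se)
  expect_error(translocation_velocity(s3[1:5, ]), "fewer than 10")
})

test_that("gyration anisotropy: planted Gaussian clouds with sigma_x^2 = 2 sigma_y^2", {
  withr::with_seed(3, {
    n_frames <- 400
    g <- t(vapply(seq_len(n_frames), function(i) {
      x <- rnorm(200, 0, sqrt(2)); y <- rnorm(200); z <- rnorm(200)
      c(mean((x - mean(x))^2), mean((y - mean(y))^2), mean((z - mean(z))^2))
    }, numeric(3)))
  })
  s <- synth_samples(n = 400)
  s$g_xx <- g[, 1]; s$g_yy <- g[, 2]; s$g_zz <- g[, 3]
  an <- gyration_anisotropy(s)
  expect_lt(abs(an$ratio - 2), 4 * an$se + 0.1)
  # rigid rod along x: ratio is huge
  rod <- s; rod$g_xx <- 100; rod$g_yy <- 1e-4
  expect_gt(gyration_anisotropy(rod)$ratio, 1e4)
})

test_that("penetration depth is recomputable by direct percentile arithmetic", {
  st <- make_tiny_state(n_fil = 2, len = 6, n_parb = 10, n_bind = 10)
  # plant bound ParB subunits spanning [tip, tip + 3a]: put them at the
  # binding minimum distance from filament subunits so they bind
  ff <- ff_default
  idsB <- st$chains[[3]]
  tipx <- mean(vapply(st$chains[1:2], function(ch) st$pos[ch[1], 1], numeric(1)))
  xs <- seq(0, 3, length.out = length(idsB))
  st$pos[idsB, ] <- cbind(xs, 0.75, 0)
  st$pol[idsB, ] <- matrix(rep(c(0, -1, 0), each = length(idsB)), ncol = 3)
  # make filament polarizations point at the ParB row
  for (ch in st$chains[1:2]) st$pol[ch, ] <- matrix(rep(c(0, 1, 0), each = length(ch)), ncol = 3)
  st$pos[st$chains[[2]], 2] <- 1.5
  pd <- penetration_depth(st, ff)
  expect_false(pd$none_bound)
  tf <- total_forces(st, ff)
  bound <- which(st$species == "PARB_BIND" & tf$min_pair_energy <= -0.5)
  oracle <- max(0, unname(quantile(st$pos[bound, 1], 0.9)) - tipx)
  expect_equal(pd$delta, oracle)
  # nothing bound: zero with flag
  far <- st; far$pos[idsB, 2] <- 50
  pdf <- penetration_depth(far, ff)
  expect_equal(pdf$delta, 0)
  expect_true(pdf$none_bound)
})

test_that("concentration profile of an intact static bundle equals its translated density", {
  cfg <- small_config(n_fil = 3, len = 10, parb = 10, bind = 6, n_relax = 0,
                      forcefield = list(eps_b = 0))
  cfg$integrator$kT <- 0 # frozen configuration
  st <- build_system(cfg, seed = 40)
  run <- run_simulation(cfg, seed = 41, state = st, n_steps = 200,
                        sample_stride = 50, frame_stride = 50)
  prof <- concentration_profile(run, bin_width = 1)
  # integral equals the polymerized ParA count
  expect_equal(sum(prof$profile$mean_density), 30)
  # frozen system: the profile is the bundle histogram shifted by the COM
  comx <- mean(st$pos[st$species != "PARA", 1])
  rel <- st$pos[st$species == "PARA", 1] - comx
  expect_equal(sum(prof$profile$mean_density[prof$profile$bin_center > 0]),
               sum(rel > 0))
})

test_that("detachment statistics: zero binding energy detaches immediately, bound runs are censored", {
  cfg0 <- small_config(n_fil = 2, len = 8, parb = 12, bind = 8, n_relax = 500,
                       forcefield = list(eps_b = 0),
                       geometry = list(parb_start_offset = 6))
  cfg0$integrator$n_steps <- 4000
  runs <- lapply(1:3, function(s) run_simulation(cfg0, seed = 50 + s,
                                                 sample_stride = 100))
  det <- detachment_statistics(runs, dwell = 0.5)
  expect_false(any(det$censored))
  expect_lt(det$mean, 2)
  # a well-bound run with chemistry off never detaches: censored flag
  cfg1 <- small_config(n_fil = 2, len = 8, parb = 12, bind = 8, n_relax = 2000)
  cfg1$chemistry$chemistry_on <- FALSE
  run1 <- run_simulation(cfg1, seed = 60, n_steps = 4000, sample_stride = 100)
  det1 <- detachment_statistics(list(run1))
  expect_true(det1$all_censored)
})

test_that("unanchored speeds reuse a fixed id set and report both drags", {
  cfg <- small_config("unanchored", n_fil = 3, len = 10, parb = 20, bind = 12,
                      n_relax = 2000, chemistry = list(k_d = 5e-3, k_h = 0.05))
  run <- run_simulation(cfg, seed = 70, n_steps = 30000, sample_stride = 500,
                        frame_stride = 1000)
  sp <- unanchored_speeds(run)
  expect_true(is.finite(sp$v_parb) && is.finite(sp$v_para))
  expect_equal(sp$gamma_B, sum(run$state$alpha[run$state$species != "PARA"]))
  expect_lte(sp$gamma_A, 30)
})
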
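# companion analytic theory

test_that("relaxation time scales as n gamma Rg^2 / kT", {
  tau <- relaxation_time(25, 5, 2)
  expect_equal(relaxation_time(25, 5, 4), 4 * tau)
  expect_equal(relaxation_time(50, 5, 2), 2 * tau)
  expect_equal(tau, 25 * 5 * 4)
})

test_that("maximum disassembly rate: limits and monotonicity", {
  expect_equal(max_disassembly_rate(k_h = 0, k_d = 1, delta = 3), 0)
  expect_equal(max_disassembly_rate(k_h = Inf, k_d = 1, delta = 3), 1)
  kh <- 10^seq(-3, 1, length.out = 40) # 1e4-fold sweep
  km <- vapply(kh, max_disassembly_rate, numeric(1), k_d = 0.5, delta = 3)
  expect_true(all(diff(km) > 0))
  expect_true(all(km <= 0.5))
  # linear in k_h as k_h -> 0 (slope delta/lambda)
  expect_equal(km[1] / kh[1], 3, tolerance = 0.01)
})

test_that("velocity regimes at the asymptotic limits", {
  lo <- velocity_regime(k_max = 1e-3, tau = 1)
  expect_equal(lo$regime, "I")
  expect_equal(lo$v_pred, 1e-3)
  hi <- velocity_regime(k_max = 1e3, tau = 1)
  expect_equal(hi$regime, "III")
  expect_equal(hi$v_pred, 0)
  expect_true(hi$detach)
  mid <- velocity_regime(k_max = 1, tau = 1)
  expect_equal(mid$regime, "II")
  expect_true(mid$v_is_bound)
})

test_that("effective potential: far-field zero, work term, Monte-Carlo bound-count oracle", {
  expect_equal(effective_potential(-1e3, F = 0, eps_b = 10, N_B = 50, Rg_x = 3), 0,
               tolerance = 1e-8)
  # dU/dF = -x at fixed x
  x <- 2.3; h <- 1e-6
  dUdF <- (effective_potential(x, F = h) - effective_potential(x, F = -h)) / (2 * h)
  expect_equal(dUdF, -x, tolerance = 1e-6)
  # N_bound(x) = N_B Phi(x/Rg) vs direct Monte-Carlo count of a planted
  # Gaussian cloud overlapping the bundle half-line
  withr::with_seed(80, {
    for (x0 in c(-2, 0, 1.5)) {
      counts <- mean(replicate(400, sum(rnorm(50, x0, 3) >= 0)))
      model <- 50 * pnorm(x0 / 3)
      expect_lt(abs(counts - model) / 50, 0.02)
    }
  })
})

test_that("Kramers escape time: Arrhenius scaling and force monotonicity", {
  mk <- function(dU) {
    # tilted-binding potential tuned to the requested barrier height
    f <- function(Fp) parabd:::escape_time_at_force(Fp, eps_b = 1.2, N_B = 20,
                                                    Rg_x = 3, gamma = 2)
    Fp <- uniroot(function(Fp) f(Fp)$barrier_height - dU, c(0.05, 3))$root
    list(F = Fp, esc = f(Fp))
  }
  e3 <- mk(3); e5 <- mk(5)
  # adding barrier height multiplies t_esc by ~exp(dU_extra) (curvature
  # factors drift slowly with F)
  expect_equal(log(e5$esc$t_esc / e3$esc$t_esc), 2, tolerance = 0.35)
  # t_esc strictly decreasing in the pulling force
  Fs <- seq(0.2, 2.5, length.out = 10)
  ts <- vapply(Fs, function(Fp) parabd:::escape_time_at_force(
    Fp, eps_b = 1.2, N_B = 20, Rg_x = 3, gamma = 2)$t_esc, numeric(1))
  expect_true(all(diff(ts) < 0))
  # beyond the critical force the barrier is flagged gone
  over <- parabd:::escape_time_at_force(10, eps_b = 1.2, N_B = 20, Rg_x = 3,
                                        gamma = 2)
  expect_true(over$no_barrier)
})

test_that("detachment force: monotone decreasing in the required crossing time", {
  F1 <- detachment_force(eps_b = 1.2, N_B = 20, Rg_x = 3, gamma = 10,
                         t_trans = 1e3)$F_detach
  F2 <- detachment_force(eps_b = 1.2, N_B = 20, Rg_x = 3, gamma = 10,
                         t_trans = 1e5)$F_detach
  F3 <- detachment_force(eps_b = 1.2, N_B = 20, Rg_x = 3, gamma = 10,
                         t_trans = 1e8)$F_detach
  expect_gt(F1, F2)
  expect_gt(F2, F3)
})

test_that("unanchored force balance ratio", {
  expect_equal(unanchored_ratio(1, 1), 1)
  expect_equal(unanchored_ratio(10, 1), 10)
  expect_error(unanchored_ratio(-1, 1))
})

test_that("theory report assembles a consistent summary for a scenario", {
  th <- theory_report(scenario("standard"))
  expect_true(th$tau > 0 && th$k_max > 0)
  expect_equal(th$kD_tau, th$k_max * th$tau)
  expect_true(th$regime %in% c("I", "II", "III"))
  if (th$regime != "III") expect_gt(th$F_detach, 0)
  # dimensional consistency: rescaling gamma rescales tau linearly
  cfg <- scenario("standard")
  cfg$integrator$gamma0 <- 2
  expect_equal(theory_report(cfg)$tau, 2 * th$tau)
})
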
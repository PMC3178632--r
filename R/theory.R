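#' Stretching relaxation time of a peripheral ParB segment
#'
#' The undecorated peripheral segments of the ParB polymer are the first to
#' stretch when the chain is pulled too fast.  Modeling a segment as an
#' entropic spring of constant `kT / Rg_x^2` loaded by its internal drag
#' `n_segment * gamma_per_subunit` gives the relaxation time
#' `tau = prefactor * n_segment * gamma_per_subunit * Rg_x^2 / kT`.
#'
#' @param n_segment subunits in one peripheral segment.
#' @param gamma_per_subunit drag per segment subunit (alpha * gamma0).
#' @param Rg_x equilibrium x radius of gyration of the segment (a).
#' @param kT thermal energy.
#' @param prefactor order-unity constant (exposed; default 1).
#' @return relaxation time tau (tau0).
#' @export
relaxation_time <- function(n_segment, gamma_per_subunit, Rg_x, kT = 1,
                            prefactor = 1) {
  stopifnot(n_segment > 0, gamma_per_subunit > 0, Rg_x > 0, kT > 0)
  prefactor * n_segment * gamma_per_subunit * Rg_x^2 / kT
}

#' Maximum disassembly rate
#'
#' Serial-rate form combining depolymerization and penetration-limited
#' hydrolysis: `k_max = [1/k_d + 1/(k_h * delta/lambda)]^-1`.  Linear in
#' `k_h` for small hydrolysis rates and saturating at `k_d` as
#' `k_h -> Inf`.
#'
#' @param k_h hydrolysis rate.
#' @param k_d depolymerization rate.
#' @param delta penetration depth (a); its saturation value is the
#'   equilibrium `Rg_x` of the polymer.
#' @param lambda fit length scale (a); default the subunit diameter.
#' @return k_max (1/tau0).
#' @export
max_disassembly_rate <- function(k_h, k_d, delta, lambda = 1) {
  stopifnot(k_h >= 0, k_d >= 0, delta > 0, lambda > 0)
  if (k_h == 0 || k_d == 0) return(0)
  1 / (1 / k_d + lambda / (k_h * delta))
}

#' Three-regime translocation velocity law
#'
#' The product `k_max * tau` of the disassembly rate and the polymer
#' relaxation time controls translocation: regime I (`k_max tau` below the
#' low threshold) -- the coil keeps its equilibrium shape and moves at
#' `v = a k_max`; regime II (order unity) -- the polymer stretches and the
#' velocity drops below `a k_max` (reported as an upper bound); regime III
#' (above the high threshold) -- the polymer elongates, binds too few ParA
#' subunits and detaches (`v = 0`).
#'
#' @param k_max maximum disassembly rate.
#' @param tau relaxation time.
#' @param a subunit diameter.
#' @param thresholds `c(low, high)` boundaries standing in for the
#'   much-less / much-greater conditions.
#' @return list with `kD_tau`, `regime` (`"I"`, `"II"`, `"III"`), `v_pred`,
#'   `v_is_bound` (TRUE in regime II where `a k_max` is an upper bound) and
#'   `detach` flag.
#' @export
velocity_regime <- function(k_max, tau, a = 1, thresholds = c(0.1, 10)) {
  kt <- k_max * tau
  if (kt < thresholds[1]) {
    list(kD_tau = kt, regime = "I", v_pred = a * k_max, v_is_bound = FALSE,
         detach = FALSE)
  } else if (kt <= thresholds[2]) {
    list(kD_tau = kt, regime = "II", v_pred = a * k_max, v_is_bound = TRUE,
         detach = FALSE)
  } else {
    list(kD_tau = kt, regime = "III", v_pred = 0, v_is_bound = FALSE,
         detach = TRUE)
  }
}

#' Effective potential of the bound ParB polymer
#'
#' The ParB subunits lie approximately in a Gaussian cloud of width `Rg_x`
#' about the center of mass; with the bundle occupying the half-line x >= 0
#' (free tips at the origin), the expected bound count is
#' `N_bound(x) = N_B * pnorm(x / Rg_x)` and
#' `U_eff(x) = -eps_b N_bound(x) - F x`.  A force pulling the polymer away
#' from the bundle (toward -x) is a negative `F` in this convention, so
#' `dU_eff/dF = -x`.
#'
#' @param x_com ParB center-of-mass coordinate(s), relative to the tip plane.
#' @param F applied force (kT/a); negative pulls away from the bundle.
#' @param eps_b binding energy per bound subunit (kT).
#' @param N_B binding-strip size (subunits).
#' @param Rg_x x radius of gyration of the polymer cloud (a).
#' @return U_eff evaluated at `x_com` (kT).
#' @export
effective_potential <- function(x_com, F = 0, eps_b = 10, N_B = 50, Rg_x = 3) {
  -eps_b * N_B * pnorm(x_com / Rg_x) - F * x_com
}

#' Kramers escape time from a metastable well
#'
#' Standard overdamped two-curvature expression
#' `t_esc = 2 pi gamma / sqrt(U''(x_w) |U''(x_b)|) * exp(dU / kT)`
#' for escape toward -x over the barrier of a tabulated or functional
#' potential.  When the applied force has erased the barrier the function
#' falls back to the drift time over the scanned interval and flags it.
#'
#' @param U function of one variable (the potential, kT).
#' @param gamma drag of the escaping body.
#' @param kT thermal energy.
#' @param interval `c(lo, hi)` scan interval containing barrier and well.
#' @param n_grid scan resolution.
#' @return list with `t_esc`, `x_well`, `x_barrier`, `barrier_height`,
#'   `no_barrier`, `low_barrier` (TRUE when below 2 kT, where the formula
#'   degrades).
#' @export
kramers_escape_time <- function(U, gamma, kT = 1, interval = c(-25, 25),
                                n_grid = 4001) {
  x <- seq(interval[1], interval[2], length.out = n_grid)
  u <- U(x)
  # locate the barrier/well pair by stationary-point structure: escape runs
  # toward -x, so the metastable well is the interior local minimum and the
  # barrier the interior local maximum immediately on its -x side
  du_sign <- sign(diff(u))
  flips <- which(du_sign[-1] * du_sign[-length(du_sign)] < 0) + 1L
  maxima <- flips[du_sign[flips - 1] > 0]
  minima <- flips[du_sign[flips - 1] < 0]
  ib <- iw <- NA_integer_
  for (m in rev(maxima)) {
    after <- minima[minima > m]
    if (length(after)) { ib <- m; iw <- after[1]; break }
  }
  if (is.na(ib) || u[ib] - u[iw] <= 0) {
    # the applied force has erased the barrier: drift-dominated escape over
    # the scanned interval (flagged)
    iw0 <- which.min(abs(x))
    drop <- max(u[iw0] - u[1], 1e-12)
    L <- x[iw0] - x[1]
    return(list(t_esc = gamma * L^2 / drop, x_well = x[iw0],
                x_barrier = NA_real_, barrier_height = 0,
                no_barrier = TRUE, low_barrier = TRUE))
  }
  x_well <- x[iw]; x_barrier <- x[ib]
  dU <- u[ib] - u[iw]
  h <- (interval[2] - interval[1]) / (n_grid - 1)
  curv <- function(i) (u[i + 1] - 2 * u[i] + u[i - 1]) / h^2
  kw <- abs(curv(iw)); kb <- abs(curv(ib))
  if (kw < 1e-12 || kb < 1e-12)
    stop("degenerate curvature at well or barrier; widen the interval")
  list(t_esc = 2 * pi * gamma / sqrt(kw * kb) * exp(dU / kT),
       x_well = x_well, x_barrier = x_barrier, barrier_height = dU,
       no_barrier = FALSE, low_barrier = dU < 2 * kT)
}

escape_time_at_force <- function(F_pull, eps_b, N_B, Rg_x, gamma, kT = 1) {
  U <- function(x) effective_potential(x, F = -F_pull, eps_b = eps_b,
                                       N_B = N_B, Rg_x = Rg_x)
  kramers_escape_time(U, gamma, kT, interval = c(-10 * Rg_x, 10 * Rg_x))
}

#' Detachment force
#'
#' The force at which the Kramers escape time of the bound polymer equals
#' the time `t_trans` required to translocate across the cell, found by
#' bisection in the pulling-force magnitude.
#'
#' @param eps_b binding energy per subunit (kT).
#' @param N_B binding-strip size.
#' @param Rg_x polymer cloud width (a).
#' @param gamma total drag of the ParB polymer.
#' @param t_trans required crossing time (tau0).
#' @param kT thermal energy.
#' @param tol relative bisection tolerance.
#' @return list with `F_detach` (kT/a, pulling magnitude), the bracket, and
#'   the escape times at the bracket ends.
#' @export
detachment_force <- function(eps_b, N_B, Rg_x, gamma, t_trans, kT = 1,
                             tol = 1e-4) {
  stopifnot(t_trans > 0)
  F_max <- eps_b * N_B / (Rg_x * sqrt(2 * pi)) # barrier vanishes above this
  f <- function(Fp) log(escape_time_at_force(Fp, eps_b, N_B, Rg_x, gamma, kT)$t_esc) -
    log(t_trans)
  lo <- 1e-6 * F_max; hi <- F_max * (1 - 1e-6)
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0)
    return(list(F_detach = 0, bracket = c(0, lo), note = "escape faster than t_trans even unloaded"))
  if (fhi > 0)
    return(list(F_detach = F_max, bracket = c(hi, F_max),
                note = "barrier survives t_trans at every subcritical force"))
  root <- uniroot(f, c(lo, hi), tol = tol * F_max)
  list(F_detach = root$root, bracket = c(lo, hi),
       t_esc = escape_time_at_force(root$root, eps_b, N_B, Rg_x, gamma, kT)$t_esc)
}

#' Speed ratio of an unanchored bundle and its ParB load
#'
#' With only internal (action-reaction) forces between the two bodies, the
#' overdamped balance gives equal and opposite forces, so
#' `|v_B| / |v_A| = gamma_A / gamma_B` with opposite signs.
#'
#' @param gamma_A,gamma_B total drags of the ParA bundle and ParB polymer.
#' @return the speed ratio `|v_B|/|v_A|`.
#' @export
unanchored_ratio <- function(gamma_A, gamma_B) {
  stopifnot(gamma_A > 0, gamma_B > 0)
  gamma_A / gamma_B
}

#' Analytic summary for a configuration
#'
#' Assembles the companion theory for a scenario: the peripheral-segment
#' relaxation time, the maximum disassembly rate, the velocity regime, and
#' the Kramers detachment force for a crossing over the bundle length.
#'
#' @param config a configuration (see [scenario()]).
#' @param Rg_x optional measured x radius of gyration; default the
#'   ideal-coil estimate `sqrt(n/6)` for the relevant segment.
#' @return list of class `pb_theory` with `tau`, `k_max`, `kD_tau`,
#'   `regime`, `v_pred`, `t_trans`, `F_detach`, `gamma_B`.
#' @export
theory_report <- function(config, Rg_x = NULL) {
  config <- validate_config(config)
  g <- config$geometry; ff <- config$forcefield; ch <- config$chemistry
  kT <- config$integrator$kT; gamma0 <- config$integrator$gamma0
  n_seg <- max(1, floor((g$parb_total_length - g$parb_binding_length) / 2))
  seg_Rg <- sqrt(n_seg / 6) * ff$a
  if (is.null(Rg_x)) Rg_x <- sqrt(g$parb_total_length / 6) * ff$a
  tau <- relaxation_time(n_seg, g$alpha_inert * gamma0, seg_Rg, kT)
  k_max <- max_disassembly_rate(ch$k_h, ch$k_d, delta = Rg_x, lambda = ff$a)
  reg <- velocity_regime(k_max, tau, a = ff$a)
  gamma_B <- gamma0 * (g$parb_binding_length * g$alpha_parb +
                         (g$parb_total_length - g$parb_binding_length) * g$alpha_inert)
  t_trans <- if (reg$v_pred > 0) g$filament_length * ff$a / reg$v_pred else NA_real_
  Fd <- if (is.finite(t_trans))
    detachment_force(ff$eps_b, g$parb_binding_length, Rg_x, gamma_B, t_trans, kT)
  else list(F_detach = NA_real_)
  structure(list(tau = tau, k_max = k_max, kD_tau = reg$kD_tau,
                 regime = reg$regime, v_pred = reg$v_pred,
                 t_trans = t_trans, F_detach = Fd$F_detach,
                 gamma_B = gamma_B, Rg_x = Rg_x, n_segment = n_seg),
            class = "pb_theory")
}

#' @export
print.pb_theory <- function(x, ...) {
  cat(sprintf("tau = %.3g tau0 | k_max = %.3g /tau0 | k_max*tau = %.3g -> regime %s\n",
              x$tau, x$k_max, x$kD_tau, x$regime))
  cat(sprintf("v_pred = %.3g a/tau0 | t_trans = %.3g tau0 | F_detach = %.3g kT/a\n",
              x$v_pred, x$t_trans, x$F_detach))
  invisible(x)
}
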
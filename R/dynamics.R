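#' Integrator parameters
#'
#' First-order Euler-Maruyama discretization of overdamped Langevin
#' (Brownian) dynamics.  Positions advance by `F dt/(alpha gamma0)` plus a
#' Gaussian kick of variance `2 kT dt/(alpha gamma0)` per component;
#' polarization vectors rotate with angular velocity `T/gamma_rot` plus
#' rotational noise of variance `2 kT dt/gamma_rot` per axis and are
#' renormalized, which preserves unit length exactly.
#'
#' @param dt time step (tau0).  Default 1e-3: small enough that the stiffest
#'   default interaction relaxes over many steps and the per-step thermal
#'   displacement stays well under 0.1 a.
#' @param kT thermal energy (the energy unit).
#' @param gamma0 reference translational drag (kT tau0/a^2 = 1 in simulation
#'   units).
#' @param gamma_rot rotational drag; default `gamma0 a^2/3`, the stick
#'   boundary ratio for a sphere of diameter a.
#' @param seed integer seed; fully determines the noise stream.
#' @param n_steps number of steps.
#' @param sample_stride observable sampling stride (steps).
#' @param bound_cut energy magnitude (kT) above which a ParB-ParA pair counts
#'   as bound for observables.
#' @param tau0 characteristic time a^2/D0 (unity in simulation units).
#' @return an object of class `pb_integrator`.
#' @export
integrator_params <- function(dt = 1e-3, kT = 1, gamma0 = 1, gamma_rot = 1 / 3,
                              seed = 1L, n_steps = 1000L, sample_stride = 100L,
                              bound_cut = 0.5, tau0 = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (kT < 0 || gamma0 <= 0 || gamma_rot <= 0) stop("invalid thermostat parameters")
  p <- list(dt = dt, kT = kT, gamma0 = gamma0, gamma_rot = gamma_rot,
            seed = as.integer(seed), n_steps = n_steps,
            sample_stride = as.integer(sample_stride), bound_cut = bound_cut,
            tau0 = tau0)
  class(p) <- "pb_integrator"
  p
}

#' Deterministic Gaussian thermal kicks
#'
#' i.i.d. zero-mean Gaussian increments with the requested variance; the same
#' seed always yields the identical stream.
#'
#' @param n number of draws.
#' @param variance variance of each draw (>= 0; 0 gives exact zeros).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
sample_thermal_kicks <- function(n, variance, seed = 1L) {
  gauss_stream_cpp(as.integer(n), variance, as.integer(seed))
}

#' Single Brownian-dynamics step (reference implementation)
#'
#' Advances a state by one Euler-Maruyama step given precomputed forces and
#' torques (e.g. from [total_forces()]).  Anchored subunits do not move.
#' This is the reference R implementation of the update rule; production
#' runs use the identical rule inside the compiled loop of
#' [run_simulation()].
#'
#' @param state a [pb_state()].
#' @param forces N x 3 force matrix.
#' @param torques N x 3 torque matrix.
#' @param params an [integrator_params()] object.
#' @param seed seed for this step's noise (defaults to `params$seed`).
#' @return the updated `pb_state` (time advanced by `dt`).
#' @export
bd_step <- function(state, forces, torques, params, seed = params$seed) {
  n <- n_subunits(state)
  dt <- params$dt
  mob <- dt / (state$alpha * params$gamma0)
  free <- !state$anchored
  noise <- matrix(0, n, 3)
  rot_noise <- matrix(0, n, 3)
  if (params$kT > 0) {
    stream <- sample_thermal_kicks(6 * n, 1, seed)
    noise <- matrix(stream[1:(3 * n)], n, 3) * sqrt(2 * params$kT * mob)
    rot_noise <- matrix(stream[(3 * n + 1):(6 * n)], n, 3) *
      sqrt(2 * params$kT * dt / params$gamma_rot)
  }
  pos <- state$pos
  pos[free, ] <- pos[free, , drop = FALSE] +
    forces[free, , drop = FALSE] * mob[free] + noise[free, , drop = FALSE]
  pol <- state$pol
  omega <- torques * (dt / params$gamma_rot) + rot_noise
  for (i in which(free)) {
    th <- sqrt(sum(omega[i, ]^2))
    if (th > 1e-14) {
      ax <- omega[i, ] / th
      p <- pol[i, ]
      pn <- cos(th) * p + sin(th) * c(ax[2] * p[3] - ax[3] * p[2],
                                      ax[3] * p[1] - ax[1] * p[3],
                                      ax[1] * p[2] - ax[2] * p[1]) +
        (1 - cos(th)) * sum(ax * p) * ax
      pol[i, ] <- pn / sqrt(sum(pn^2))
    }
  }
  state$pos <- pos
  state$pol <- pol
  state$time <- state$time + dt
  state
}
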
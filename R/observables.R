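samples_of <- function(x) {
  if (inherits(x, "pb_run")) x$samples else as.data.frame(x)
}

in_window <- function(s, window) {
  if (is.null(window)) rep(TRUE, nrow(s)) else s$time >= window[1] & s$time <= window[2]
}

#' Translocation velocity
#'
#' Least-squares slope of the ParB center-of-mass x coordinate over a time
#' window, with a block-bootstrap standard error (contiguous blocks resampled
#' with replacement, so the error is robust to the strong autocorrelation of
#' an attached polymer's COM).
#'
#' @param x a `pb_run` or its samples data.frame.
#' @param window `c(t0, t1)` time window (default: all samples).
#' @param n_boot bootstrap replicates.
#' @param n_blocks bootstrap block count.
#' @param seed bootstrap seed.
#' @return list with `v` (a/tau0), `se`, and `n` (samples used).
#' @export
translocation_velocity <- function(x, window = NULL, n_boot = 200,
                                   n_blocks = 10, seed = 1L) {
  s <- samples_of(x)
  s <- s[in_window(s, window), ]
  if (nrow(s) < 10) stop("window holds fewer than 10 samples")
  fit <- coef(lm(parb_x ~ time, data = s))[2]
  blocks <- split(seq_len(nrow(s)), cut(seq_len(nrow(s)), n_blocks, labels = FALSE))
  vs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(blocks[sample.int(n_blocks, n_blocks, replace = TRUE)])
      coef(lm(parb_x ~ time, data = s[idx, ]))[2]
    }, numeric(1))
  })
  list(v = unname(fit), se = sd(vs), n = nrow(s))
}

#' Gyration anisotropy of the ParB polymer
#'
#' Time-averaged ratio of the longitudinal (x) to transverse (y) diagonal
#' gyration-tensor components; 1 for an isotropic coil, large for a chain
#' stretched along the axis of motility.
#'
#' @inheritParams translocation_velocity
#' @param n_blocks blocks for the standard error of the ratio.
#' @return list with `ratio`, `se`, `n`.
#' @export
gyration_anisotropy <- function(x, window = NULL, n_blocks = 10) {
  s <- samples_of(x)
  s <- s[in_window(s, window), ]
  if (nrow(s) < 4) stop("need at least 4 samples for the anisotropy ratio")
  n_blocks <- max(2, min(n_blocks, floor(nrow(s) / 2)))
  ratio <- mean(s$g_xx) / mean(s$g_yy)
  idx <- cut(seq_len(nrow(s)), n_blocks, labels = FALSE)
  br <- vapply(split(seq_len(nrow(s)), idx),
               function(i) mean(s$g_xx[i]) / mean(s$g_yy[i]), numeric(1))
  list(ratio = ratio, se = sd(br) / sqrt(length(br)), n = nrow(s))
}

#' Penetration depth of the ParB polymer into the bundle
#'
#' `delta = max(0, x_q90(bound ParB subunits) - mean x of the filaments'
#' free-tip subunits)`.  The 90th percentile (rather than the maximum) makes
#' the estimate robust to single-subunit excursions.
#'
#' @param state a [pb_state()].
#' @param params a [ff_params()] object.
#' @param chem optional [chemistry_params()] (binding eligibility).
#' @param bound_cut pair-energy magnitude (kT) defining "bound".
#' @return list with `delta` and `none_bound` flag.
#' @export
penetration_depth <- function(state, params, chem = NULL, bound_cut = 0.5) {
  tf <- total_forces(state, params, chem)
  bound <- which(state$species == "PARB_BIND" & tf$min_pair_energy <= -bound_cut)
  anyA <- state$chain_anchored &
    vapply(state$chains, function(ch) length(ch) >= 2 && state$species[ch[1]] == "PARA",
           logical(1))
  use <- if (any(anyA)) which(anyA) else
    which(vapply(state$chains, function(ch)
      length(ch) > 0 && state$species[ch[1]] == "PARA", logical(1)))
  tipx <- mean(vapply(state$chains[use], function(ch) state$pos[ch[1], 1], numeric(1)))
  if (length(bound) == 0) return(list(delta = 0, none_bound = TRUE))
  xq <- unname(quantile(state$pos[bound, 1], 0.9, type = 7))
  list(delta = max(0, xq - tipx), none_bound = FALSE)
}

#' Co-moving ParA concentration profile
#'
#' Histogram of polymerized ParA subunit x positions relative to the
#' instantaneous ParB center of mass, averaged over trajectory frames.
#' During steady translocation the profile is stationary and front-loaded
#' (more ParA ahead of the ParB COM, +x side, than behind).
#'
#' @param run a `pb_run` with stored frames.
#' @param window optional `c(t0, t1)` restricting the frames.
#' @param bin_width histogram bin width (a).
#' @param breaks optional explicit breaks (overrides `bin_width`).
#' @return list with `profile` (data.frame `bin_center`, `mean_density`),
#'   `window`, `n_frames`; the integral of the profile equals the mean
#'   polymerized ParA count in the window.
#' @export
concentration_profile <- function(run, window = NULL, bin_width = 1, breaks = NULL) {
  if (length(run$frames) == 0) stop("run has no stored frames (set frame_stride)")
  sp <- run$state$species
  times <- vapply(run$frames, function(f) f$time, numeric(1))
  keep <- if (is.null(window)) rep(TRUE, length(times)) else
    times >= window[1] & times <= window[2]
  frames <- run$frames[keep]
  if (length(frames) == 0) stop("no frames in window")
  rel <- lapply(frames, function(f) {
    poly <- f$chain_id > 0 & sp == "PARA"
    comx <- mean(f$pos[sp != "PARA", 1])
    f$pos[poly, 1] - comx
  })
  allx <- unlist(rel)
  if (is.null(breaks)) {
    lo <- floor(min(allx)) - bin_width
    hi <- ceiling(max(allx)) + bin_width
    breaks <- seq(lo, hi, by = bin_width)
  }
  counts <- rowMeans(vapply(rel, function(x)
    hist(x, breaks = breaks, plot = FALSE)$counts, numeric(length(breaks) - 1)))
  list(profile = data.frame(bin_center = (head(breaks, -1) + tail(breaks, -1)) / 2,
                            mean_density = counts / diff(breaks)),
       window = if (is.null(window)) range(times) else window,
       n_frames = length(frames))
}

#' Detachment statistics over replicate runs
#'
#' Detachment (from the anchored main bundle) is scored at the first sample
#' time from which the count of ParB subunits bound to anchored-bundle ParA
#' stays zero and the ParB COM stays farther than `range_b + a` from every
#' anchored-bundle subunit for a sustained dwell; runs with no such time are
#' right-censored at their final sample.  Binding to severed, unanchored
#' fragments does not count as attachment (the severing failure mode carries
#' ParB away on fragments).  In unanchored scenarios all ParA chains count
#' as the bundle.
#'
#' @param runs list of `pb_run` objects (replicates with distinct seeds).
#' @param dwell sustained-detachment dwell time (tau0); long enough that
#'   brief unbinding excursions with prompt recapture do not count.
#' @return list with `times`, `censored` (logical), `mean`, `se` (censored
#'   times enter at their horizon, so the mean is a lower bound when any run
#'   is censored), and `all_censored`.
#' @export
detachment_statistics <- function(runs, dwell = 10) {
  if (inherits(runs, "pb_run")) runs <- list(runs)
  res <- lapply(runs, function(run) {
    s <- run$samples
    far <- run$config$forcefield$range_b + run$config$forcefield$a
    cond <- s$n_bound_anchored == 0 & (is.na(s$dmin_com) | s$dmin_com > far)
    t_end <- tail(s$time, 1)
    # "first detachment" presumes attachment: scan from the first bound
    # sample; a run that never attaches detaches at its first sample
    first_attached <- which(s$n_bound_anchored > 0)[1]
    if (is.na(first_attached)) return(c(time = s$time[1], censored = 0))
    idx <- which(cond & seq_along(cond) >= first_attached)
    for (i in idx) {
      w <- s$time >= s$time[i] & s$time <= s$time[i] + dwell
      if (all(cond[w]) && (s$time[i] + dwell) <= t_end)
        return(c(time = s$time[i], censored = 0))
    }
    c(time = t_end, censored = 1)
  })
  m <- do.call(rbind, res)
  times <- m[, "time"]; cens <- m[, "censored"] == 1
  list(times = times, censored = cens,
       mean = mean(times), se = sd(times) / sqrt(length(times)),
       all_censored = all(cens))
}

#' Force-velocity relation
#'
#' Runs the configuration over a grid of external loads (each pulling both
#' terminal ParB subunits in -x) and measures the translocation velocity and
#' detachment flag at each point.
#'
#' @param config a configuration.
#' @param forces numeric vector of load magnitudes (kT/a).
#' @param seed base seed (point i uses `seed + i`).
#' @param n_steps optional override.
#' @return data.frame with `force`, `velocity`, `velocity_se`, `detached`.
#' @export
force_velocity <- function(config, forces, seed = 1L, n_steps = NULL) {
  rows <- lapply(seq_along(forces), function(i) {
    cfg <- config
    cfg$geometry$external_force <- forces[i]
    run <- run_simulation(cfg, seed = seed + i, n_steps = n_steps)
    det <- detachment_statistics(list(run))
    v <- tryCatch(translocation_velocity(run), error = function(e) list(v = NA, se = NA))
    data.frame(force = forces[i], velocity = v$v, velocity_se = v$se,
               detached = !det$censored[1])
  })
  do.call(rbind, rows)
}

#' ParB and ParA bundle speeds in an unanchored run
#'
#' The ParB COM velocity comes from the sampled series; the bundle velocity
#' from the mean x of the subunits still polymerized at the end of the run
#' (a fixed id set, so depolymerization events do not bias the slope).
#' During pulling the two speeds have opposite signs and satisfy the
#' overdamped force balance `gamma_A v_A = -gamma_B v_B`.
#'
#' @param run a `pb_run` with stored frames.
#' @param window optional time window.
#' @return list with `v_parb`, `v_para`, their standard errors, and the
#'   window-mean total drags `gamma_A`, `gamma_B`.
#' @export
unanchored_speeds <- function(run, window = NULL) {
  if (length(run$frames) == 0) stop("run has no stored frames (set frame_stride)")
  sp <- run$state$species
  times <- vapply(run$frames, function(f) f$time, numeric(1))
  keep <- if (is.null(window)) rep(TRUE, length(times)) else
    times >= window[1] & times <= window[2]
  if (!any(keep)) stop("no frames in window")
  # fixed id set: subunits still polymerized at the window's end, so
  # depolymerization events cannot bias the slope
  final <- run$frames[[max(which(keep))]]
  ids <- which(final$chain_id > 0 & sp == "PARA")
  if (length(ids) == 0) stop("no polymerized ParA remains in the window")
  tk <- times[keep]
  mx <- vapply(run$frames[keep], function(f) mean(f$pos[ids, 1]), numeric(1))
  fitA <- lm(mx ~ tk)
  # block-bootstrap error (the naive lm error underestimates badly on an
  # autocorrelated series)
  nb <- max(2, min(10, floor(length(mx) / 3)))
  blocks <- split(seq_along(mx), cut(seq_along(mx), nb, labels = FALSE))
  vsA <- withr::with_seed(1L, vapply(1:200, function(b) {
    idx <- unlist(blocks[sample.int(nb, nb, replace = TRUE)])
    unname(coef(lm(mx[idx] ~ tk[idx]))[2])
  }, numeric(1)))
  v <- translocation_velocity(run, window = window)
  g <- run$config$geometry
  s <- run$samples[in_window(run$samples, window), ]
  gamma0 <- run$config$integrator$gamma0
  gamma_A <- mean(s$n_poly) * g$alpha_para * gamma0
  gamma_B <- sum(run$state$alpha[sp != "PARA"]) * gamma0
  list(v_parb = v$v, se_parb = v$se,
       v_para = unname(coef(fitA)[2]),
       se_para = sd(vsA),
       gamma_A = gamma_A, gamma_B = gamma_B)
}
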
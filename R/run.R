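#' Validate a configuration
#'
#' Checks section names, re-validates every section through its constructor
#' (so unknown keys are rejected with their location), fills defaults, and
#' resolves derived values (the crosslink rest length follows the filament
#' spacing; the confinement radius is copied into the force field).
#'
#' @param config a configuration list (see [scenario()]).
#' @return the validated, resolved configuration.
#' @export
validate_config <- function(config) {
  known <- c("scenario_name", "geometry", "forcefield", "chemistry",
             "integrator", "output", "sweep")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  rebuild <- function(section, ctor, drop = character(0)) {
    x <- config[[section]]
    if (is.null(x)) x <- list()
    x <- x[setdiff(names(x), drop)]
    class(x) <- NULL
    tryCatch(do.call(ctor, x),
             error = function(e) stop("in configuration section '", section,
                                      "': ", conditionMessage(e), call. = FALSE))
  }
  config$geometry <- rebuild("geometry", geometry_spec)
  config$forcefield <- rebuild("forcefield", ff_params, drop = "binding_form_code")
  config$chemistry <- rebuild("chemistry", chemistry_params,
                              drop = c("binding_mode_code", "disassembly_mode_code"))
  config$integrator <- rebuild("integrator", integrator_params)
  if (is.null(config$output)) config$output <- list()
  out_known <- c("sample_stride", "frame_stride", "dir")
  out_extra <- setdiff(names(config$output), out_known)
  if (length(out_extra))
    stop("unknown configuration key(s) in 'output': ", paste(out_extra, collapse = ", "))
  if (is.null(config$output$sample_stride)) config$output$sample_stride <- 200L
  if (is.null(config$output$frame_stride)) config$output$frame_stride <- 0L
  # resolved values
  config$forcefield$d0 <- config$geometry$spacing
  if (!is.null(config$geometry$cell_confinement))
    config$forcefield$wall_radius <- config$geometry$cell_confinement
  config
}

#' Run a simulation
#'
#' Builds (or accepts) an initial state and advances it with the compiled
#' Brownian-dynamics + chemistry loop.  The same configuration and seed
#' always produce the identical trajectory.
#'
#' @param config a configuration from [scenario()] or [read_config()].
#' @param seed integer seed (defaults to the configuration's); drives both
#'   the builder and the thermal noise.
#' @param state optional pre-built [pb_state()]; skips [build_system()].
#' @param n_steps,sample_stride,frame_stride,chemistry_on optional overrides.
#' @param track_ids subunit ids whose positions are recorded every sample.
#' @param use_neighbor_list `FALSE` forces brute-force pair evaluation.
#' @return an object of class `pb_run`: list with the resolved `config`,
#'   `seed`, final `state`, `samples` (data.frame of the observable series),
#'   `events` (data.frame), `frames` (list, if `frame_stride > 0`), `track`
#'   (matrix), and `diagnostics`.
#' @export
run_simulation <- function(config, seed = NULL, state = NULL, n_steps = NULL,
                           sample_stride = NULL, frame_stride = NULL,
                           chemistry_on = NULL, track_ids = integer(0),
                           use_neighbor_list = TRUE) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$integrator$seed
  if (is.null(state)) state <- build_system(config, seed = seed)
  integ <- config$integrator
  integ$seed <- as.integer(seed)
  if (!is.null(n_steps)) integ$n_steps <- n_steps
  integ$sample_stride <- as.integer(
    if (!is.null(sample_stride)) sample_stride else config$output$sample_stride)
  fstride <- as.integer(
    if (!is.null(frame_stride)) frame_stride else config$output$frame_stride)
  chem <- config$chemistry
  if (!is.null(chemistry_on)) chem$chemistry_on <- isTRUE(chemistry_on)

  ext <- NULL
  if (config$geometry$external_force > 0) {
    ext <- matrix(0, n_subunits(state), 3)
    for (c in seq_along(state$chains)) {
      ch <- state$chains[[c]]
      if (length(ch) && state$species[ch[1]] != "PARA") {
        ext[ch[1], 1] <- -config$geometry$external_force
        ext[ch[length(ch)], 1] <- -config$geometry$external_force
      }
    }
  }

  a <- state_args(state)
  out <- run_core_cpp(a$pos, a$pol, a$species, a$nuc, a$alpha, a$anchored,
                      a$chains, a$chainAnchored, a$xlinks, a$t, a$n_para0,
                      config$forcefield, chem, integ, ext,
                      as.integer(track_ids), use_neighbor_list, fstride)
  samples <- as.data.frame(out$samples)
  events <- as.data.frame(out$events)
  if (nrow(events)) events$kind <- .EVENT_KINDS[events$kind + 1L]
  run <- list(config = config, seed = as.integer(seed),
              state = state_from_core(state, out),
              samples = samples, events = events,
              frames = out$frames, track = out$track,
              diagnostics = list(max_step_displacement = out$max_step_displacement,
                                 n_capped = out$n_capped,
                                 n_culled = out$n_culled))
  run$state$time <- out$time
  class(run) <- "pb_run"
  run
}

#' @export
print.pb_run <- function(x, ...) {
  cat("pb_run:", x$config$scenario_name, "| seed", x$seed,
      "|", nrow(x$samples), "samples to t =", format(x$state$time), "\n")
  if (nrow(x$samples)) {
    cat(sprintf("  ParB COM x: %.2f -> %.2f a | bound: %d | polymerized ParA: %d\n",
                x$samples$parb_x[1], tail(x$samples$parb_x, 1),
                tail(x$samples$n_bound, 1), tail(x$samples$n_poly, 1)))
  }
  cat("  events:", nrow(x$events), "\n")
  invisible(x)
}

#' Run a parameter sweep
#'
#' Executes one run per sweep value (per-point seeds derived from `seed`)
#' and collects a tidy results table.
#'
#' @param config a configuration whose `sweep` entry names the parameter and
#'   values (see [scenario()]).
#' @param seed base seed; point i uses `seed + i`.
#' @param n_steps optional override applied to every point.
#' @return data.frame with the sweep value, translocation velocity and its
#'   bootstrap error, final bound count, detachment flag, and event totals.
#' @export
run_scan <- function(config, seed = 1L, n_steps = NULL) {
  sw <- config$sweep
  if (is.null(sw)) stop("configuration has no sweep; use a *_sweep scenario")
  rows <- lapply(seq_along(sw$values), function(i) {
    cfg <- apply_sweep_value(config, sw$values[i])
    run <- run_simulation(cfg, seed = seed + i, n_steps = n_steps)
    v <- tryCatch(translocation_velocity(run), error = function(e) list(v = NA, se = NA))
    det <- detachment_statistics(list(run))
    data.frame(value = sw$values[i], velocity = v$v, velocity_se = v$se,
               n_bound_final = tail(run$samples$n_bound, 1),
               detached = !det$censored[1],
               n_depoly = sum(run$events$kind == "DEPOLYMERIZATION"),
               n_sever = sum(run$events$kind == "SEVER"))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- sw$parameter
  out
}
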
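strip_config <- function(config) {
  drop <- function(x, fields) {
    x <- x[setdiff(names(x), fields)]
    class(x) <- NULL
    x
  }
  list(scenario_name = config$scenario_name,
       geometry = drop(config$geometry, character(0)),
       forcefield = drop(config$forcefield, "binding_form_code"),
       chemistry = drop(config$chemistry,
                        c("binding_mode_code", "disassembly_mode_code")),
       integrator = drop(config$integrator, character(0)),
       output = config$output,
       sweep = config$sweep)
}

#' Write a configuration to YAML
#'
#' The file holds the fully resolved configuration (defaults filled in), so
#' `write_config(read_config(path), path2)` reproduces `path` byte for byte
#' for files that were themselves written by this function.
#'
#' @param config a configuration.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(strip_config(config), path, precision = 17)
  invisible(path)
}

#' Read and validate a configuration from YAML
#'
#' Unknown keys anywhere in the file are rejected with their location;
#' missing fields take their documented defaults and are recorded as
#' resolved values.
#'
#' @param path YAML file written by [write_config()] (or hand-written in the
#'   same schema).
#' @return a validated configuration.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' Configuration hash
#' @param config a configuration.
#' @return short stable hash of the resolved configuration.
#' @export
config_hash <- function(config) {
  rlang::hash(strip_config(validate_config(config)))
}

frame_lines <- function(pos, pol, species, nucleotide, chain_id, chain_index,
                        time) {
  n <- nrow(pos)
  header <- sprintf(
    'Time=%.17g Properties=species:S:1:pos:R:3:polar:R:3:nucleotide:S:1:chain:I:1:chain_index:I:1',
    time)
  body <- sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g %s %d %d",
                  species, pos[, 1], pos[, 2], pos[, 3],
                  pol[, 1], pol[, 2], pol[, 3],
                  nucleotide, chain_id, chain_index)
  c(as.character(n), header, body)
}

#' Write an extended-XYZ trajectory
#'
#' One frame per stored snapshot, with per-atom columns species, position,
#' polarization vector, nucleotide, chain id and chain index, and the frame
#' time in the comment line.  The format is readable by standard molecular
#' viewers and by [read_trajectory()] with full precision.
#'
#' @param x a `pb_run` with stored frames, or a [pb_state()] (single frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "pb_state")) {
    m <- chain_membership(x)
    writeLines(frame_lines(x$pos, x$pol, x$species, x$nucleotide,
                           m$chain_id, m$chain_index, x$time), con)
  } else if (inherits(x, "pb_run")) {
    if (length(x$frames) == 0) stop("run has no stored frames (set frame_stride)")
    sp <- x$state$species
    for (f in x$frames) {
      nuc <- .NUC_LEVELS[f$nucleotide + 1L]
      writeLines(frame_lines(f$pos, f$pol, sp, nuc, f$chain_id, f$chain_index,
                             f$time), con)
    }
  } else stop("x must be a pb_state or pb_run")
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path file written by [write_trajectory()].
#' @param stride keep every `stride`-th frame.
#' @return list of frames, each with `time`, `pos`, `pol`, `species`,
#'   `nucleotide`, `chain_id`, `chain_index`.
#' @export
read_trajectory <- function(path, stride = 1L) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L; k <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed frame at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated frame starting at line ", i)
    header <- lines[i + 1L]
    tm <- regmatches(header, regexec("Time=([-+0-9.eE]+)", header))[[1]][2]
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(body, " +")
    get <- function(j) vapply(parts, `[[`, character(1), j)
    k <- k + 1L
    if ((k - 1L) %% stride == 0L) {
      frames[[length(frames) + 1L]] <- list(
        time = as.numeric(tm),
        pos = cbind(as.numeric(get(2)), as.numeric(get(3)), as.numeric(get(4))),
        pol = cbind(as.numeric(get(5)), as.numeric(get(6)), as.numeric(get(7))),
        species = get(1), nucleotide = get(8),
        chain_id = as.integer(get(9)), chain_index = as.integer(get(10)))
    }
    i <- i + 2L + n
  }
  frames
}

#' Write the observable series as tidy CSV
#' @param run a `pb_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_observables <- function(run, path) {
  write.csv(run$samples, path, row.names = FALSE)
  invisible(path)
}

#' Write the chemistry event log as TSV
#' @param run a `pb_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(run, path) {
  ev <- run$events
  if (nrow(ev) == 0)
    ev <- data.frame(time = numeric(0), kind = character(0),
                     subunit_id = integer(0), filament_id = integer(0))
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Full provenance for a run: resolved configuration and its hash, seed,
#' package version, and headline outcomes.
#'
#' @param run a `pb_run`.
#' @return a list serializable to JSON.
#' @export
run_manifest <- function(run) {
  list(package = "parabd",
       version = as.character(packageVersion("parabd")),
       scenario = run$config$scenario_name,
       seed = run$seed,
       config_hash = config_hash(run$config),
       config = strip_config(run$config),
       time_final = run$state$time,
       n_samples = nrow(run$samples),
       n_events = nrow(run$events))
}

#' Write a run manifest as JSON
#' @param run a `pb_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run_manifest(run), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
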
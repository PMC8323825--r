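#' Load, validate and save a run configuration
#'
#' A run configuration drives the end-to-end pipeline
#' ([run_pipeline()]): which sensing beam serves each membrane condition,
#' which calibration source converts traces, the rupture-detection
#' parameters, the study design, and the seed. Configurations are YAML;
#' unknown keys are rejected and defaults are filled in, so a minimal file
#' naming a beam is valid.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list with all defaults filled.
#' @examples
#' cfg <- default_config()
#' cfg$beam
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file `%s` does not exist.", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @export
default_config <- function() {
  as_run_config(list())
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$design <- out$design[setdiff(names(out$design), "wires")]
  yaml::write_yaml(out, path)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    beam = list(pia_only = "beam1", dura_pia = "beam3"),
    calibration_source = "fem",
    insertion_rate_um_s = 100,
    detection = list(drop_fraction = 0.05, drop_window = 0.1, min_drop = 0.2),
    design = list(animals = 8, replicates = 1),
    trace_level = TRUE,
    save_plots = FALSE,
    seed = 1L,
    outdir = NULL,
    verbosity = 1L
  )
}

as_run_config <- function(raw) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, raw)
  for (nm in names(defaults)) {
    if (!nm %in% names(cfg)) cfg[nm] <- list(defaults[[nm]])
  }
  cfg <- cfg[names(defaults)]
  if (is.character(cfg$beam)) {
    cfg$beam <- list(pia_only = cfg$beam, dura_pia = cfg$beam)
  }
  known_beams <- beam_registry()$beam
  for (b in unlist(cfg$beam)) {
    if (!b %in% known_beams) {
      abort(sprintf("Unknown beam `%s` in config; registry has: %s.",
                    b, paste(known_beams, collapse = ", ")))
    }
  }
  if (!cfg$calibration_source %in% c("fem", "ideal", "experiment")) {
    abort("`calibration_source` must be one of fem, ideal, experiment.")
  }
  known_detect <- c("drop_fraction", "drop_window", "min_drop")
  bad <- setdiff(names(cfg$detection), known_detect)
  if (length(bad) > 0) {
    abort(sprintf("Unknown detection key(s): %s.", paste(bad, collapse = ", ")))
  }
  cfg$detection <- utils::modifyList(defaults$detection, cfg$detection)
  known_design <- names(formals(study_design))
  bad <- setdiff(names(cfg$design), known_design)
  if (length(bad) > 0) {
    abort(sprintf("Unknown design key(s): %s.", paste(bad, collapse = ", ")))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  cat(sprintf("  beams: pia_only = %s, dura_pia = %s (%s calibration)\n",
              x$beam$pia_only, x$beam$dura_pia, x$calibration_source))
  cat(sprintf("  detection: drop >= max(%.0f%% of running max, %.2f mN) within %.0f ms\n",
              100 * x$detection$drop_fraction, x$detection$min_drop,
              1000 * x$detection$drop_window))
  cat(sprintf("  design: %s animals, %s replicate(s); trace-level simulation: %s\n",
              x$design$animals %||% 8, x$design$replicates %||% 1,
              x$trace_level))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
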
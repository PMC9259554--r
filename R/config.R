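#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis. The `"recommended"`
#' profile uses a relative peak-binning tolerance of 0.002 (0.2%), the
#' conventional value for linear-TOF alignment; the `"paper"` profile keeps
#' the printed tolerance of 0.2 verbatim. All other constants are shared:
#' 2,000-20,000 Da trim window, Savitzky-Golay half-window 10 / order 3,
#' 100 SNIP iterations, SNR 4 with detection half-window 40 points, 33%
#' occurrence filter, top-k up to 20, k = 3 clusters, 60/40 split,
#' 5-fold x 20-repeat cross-validation.
#'
#' @param profile `"recommended"` or `"paper"` (binning tolerance 0.002 vs
#'   0.2, both relative).
#' @param ... Named overrides of individual fields.
#' @return A list of class `pipeline_config`.
#' @export
#'
#' @examples
#' pipeline_config(snr = 5, top_k = 10)
pipeline_config <- function(profile = c("recommended", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    trim_range = c(2000, 20000),
    sg_half_window = 10L,
    sg_polyorder = 3L,
    snip_iterations = 100L,
    snr = 4,
    peak_half_window = 40L,
    bin_tolerance = if (profile == "paper") 0.2 else 0.002,
    min_occurrence_frac = 0.33,
    top_k = 20L,
    n_clusters = 3L,
    cv_folds = 5L,
    cv_repeats = 20L,
    train_frac = 0.6,
    rf_trees = 500L,
    seed = 1L,
    profile = profile
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(sprintf("Unknown config field(s): %s",
                                 paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  assert_scalar_number(cfg$sg_half_window, "sg_half_window", lower = 1)
  assert_scalar_number(cfg$peak_half_window, "peak_half_window", lower = 1)
  assert_scalar_number(cfg$snip_iterations, "snip_iterations", lower = 1)
  assert_scalar_number(cfg$bin_tolerance, "bin_tolerance")
  if (cfg$bin_tolerance <= 0) abort("`bin_tolerance` must be > 0.")
  assert_scalar_number(cfg$min_occurrence_frac, "min_occurrence_frac")
  if (cfg$min_occurrence_frac <= 0 || cfg$min_occurrence_frac >= 1) {
    abort("`min_occurrence_frac` must lie strictly between 0 and 1.")
  }
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1) {
    abort("`train_frac` must lie strictly between 0 and 1.")
  }
  if (cfg$trim_range[1] >= cfg$trim_range[2]) {
    abort("`trim_range` must be an increasing (low, high) pair.")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> profile '%s'\n", x$profile))
  flds <- setdiff(names(x), "profile")
  for (f in flds) cat(sprintf("  %-20s %s\n", f, paste(x[[f]], collapse = ", ")))
  invisible(x)
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "recommended"
  raw$profile <- NULL
  do.call(pipeline_config, c(list(profile = profile), raw))
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
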
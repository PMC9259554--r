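#' Spectrum preprocessing
#'
#' Raw linear-TOF profiles are prepared for peak detection in a fixed order:
#' square-root variance stabilisation, Savitzky-Golay smoothing, SNIP
#' baseline estimation and subtraction. Each step records itself in the
#' spectrum's `provenance` attribute so the applied order is auditable.
#'
#' @name preprocess
NULL

as_processed <- function(s) {
  if (inherits(s, "processed_spectrum")) return(s)
  m <- spectrum_meta(s)
  df <- tibble(mz = s$mz, intensity = s$intensity,
               baseline = rep(0, nrow(s)))
  new_spectrum_tbl(df, "processed_spectrum", m$sample_id, m$group,
                   m$replicate, provenance = attr(s, "provenance") %||% list())
}

add_provenance <- function(s, step, params = list()) {
  prov <- attr(s, "provenance") %||% list()
  prov[[length(prov) + 1L]] <- c(list(step = step), params)
  attr(s, "provenance") <- prov
  s
}

#' @export
print.processed_spectrum <- function(x, ...) {
  m <- spectrum_meta(x)
  steps <- vapply(attr(x, "provenance") %||% list(), function(p) p$step, "")
  cat(sprintf("<processed_spectrum> %s: %d points, steps: %s\n",
              m$sample_id, nrow(x),
              if (length(steps)) paste(steps, collapse = " -> ") else "(none)"))
  invisible(x)
}

#' Provenance of a processed spectrum
#'
#' @param s A processed spectrum.
#' @return Character vector of applied step names, in order.
#' @export
provenance_steps <- function(s) {
  vapply(attr(s, "provenance") %||% list(), function(p) p$step, "")
}

#' Square-root intensity transform
#'
#' Stabilises the count-like variance of TOF detector intensities.
#'
#' @param s A raw or processed spectrum with non-negative intensities.
#' @return A `processed_spectrum` with `intensity` replaced by its square
#'   root; masses untouched.
#' @export
sqrt_transform <- function(s) {
  if (any(s$intensity < 0)) abort("Negative intensities; cannot sqrt-transform.")
  out <- as_processed(s)
  out$intensity <- sqrt(out$intensity)
  add_provenance(out, "sqrt")
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the centre value of a least-squares polynomial fit
#' over a sliding window of `2 * half_window + 1` points. The first and last
#' half-windows are filled from the polynomial fitted to the first/last full
#' window. Delegates the filtering to [signal::sgolayfilt()], whose startup
#' and ending transients implement exactly that edge rule.
#'
#' @param s A processed (or raw) spectrum on a near-uniform m/z grid; a
#'   warning is issued if the grid spacing varies by more than 1%.
#' @param half_window Window half-width in points (default 10).
#' @param polyorder Polynomial degree (default 3); must be smaller than the
#'   window length.
#' @return The smoothed spectrum.
#' @export
savitzky_golay <- function(s, half_window = 10L, polyorder = 3L) {
  out <- as_processed(s)
  n <- nrow(out)
  wl <- 2L * as.integer(half_window) + 1L
  if (wl <= polyorder) abort("Window length must exceed `polyorder`.")
  if (n < wl) abort(sprintf(
    "Spectrum has %d points but the smoothing window needs %d.", n, wl))
  dg <- diff(out$mz)
  if (max(dg) > 1.01 * min(dg)) {
    warn("m/z grid spacing varies by more than 1%; Savitzky-Golay assumes a uniform grid.")
  }
  out$intensity <- as.numeric(
    signal::sgolayfilt(out$intensity, p = polyorder, n = wl))
  add_provenance(out, "savitzky_golay",
                 list(half_window = as.integer(half_window),
                      polyorder = as.integer(polyorder)))
}

#' SNIP baseline estimation and subtraction
#'
#' Statistics-sensitive non-linear iterative peak clipping: starting from the
#' signal itself, the running estimate at each point is replaced by the
#' minimum of itself and the mean of its two neighbours at distance `i`, for
#' window sizes `i = 1, ..., iterations` (increasing order; set
#' `decreasing = TRUE` for the reversed schedule). Boundary indices are
#' clamped. The clipped curve is stored as `baseline` and subtracted from
#' the intensity; small negative residues are clipped to zero.
#'
#' @param s A processed spectrum (typically smoothed).
#' @param iterations Number of clipping passes / maximal half-window in
#'   points (default 100).
#' @param decreasing Run the window schedule from `iterations` down to 1.
#' @return The baseline-corrected spectrum with its `baseline` column filled.
#' @export
snip_baseline <- function(s, iterations = 100L, decreasing = FALSE) {
  out <- as_processed(s)
  n <- nrow(out)
  iterations <- as.integer(iterations)
  if (iterations < 1L) abort("`iterations` must be >= 1.")
  if (iterations > n %/% 2L) {
    abort(sprintf("%d SNIP iterations exceed half the spectrum length (%d points).",
                  iterations, n))
  }
  b <- out$intensity
  idx <- seq_len(n)
  schedule <- if (decreasing) rev(seq_len(iterations)) else seq_len(iterations)
  for (i in schedule) {
    left <- b[pmax(idx - i, 1L)]
    right <- b[pmin(idx + i, n)]
    b <- pmin(b, (left + right) / 2)
  }
  out$baseline <- b
  out$intensity <- pmax(out$intensity - b, 0)
  add_provenance(out, "snip_baseline",
                 list(iterations = iterations, decreasing = decreasing))
}

#' Trim a spectrum to a mass window
#'
#' @param s A spectrum.
#' @param low,high Inclusive mass bounds in Da.
#' @return The spectrum restricted to `low <= mz <= high`.
#' @export
trim_spectrum <- function(s, low = 2000, high = 20000) {
  if (low >= high) abort("`low` must be smaller than `high`.")
  keep <- s$mz >= low & s$mz <= high
  if (!any(keep)) abort("Trim window contains no data points.")
  out <- s[keep, , drop = FALSE]
  attrs <- attributes(s)
  for (a in c("sample_id", "group", "replicate", "provenance")) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(s)
  if (inherits(out, "processed_spectrum")) {
    out <- add_provenance(out, "trim", list(low = low, high = high))
  }
  out
}

#' Run the full preprocessing chain on one spectrum
#'
#' Trim to the configured mass window, then sqrt-transform, smooth and
#' baseline-correct in that fixed order.
#'
#' @param s A raw spectrum.
#' @param config A [pipeline_config()].
#' @return A `processed_spectrum`.
#' @export
preprocess_spectrum <- function(s, config = pipeline_config()) {
  s |>
    trim_spectrum(config$trim_range[1], config$trim_range[2]) |>
    sqrt_transform() |>
    savitzky_golay(config$sg_half_window, config$sg_polyorder) |>
    snip_baseline(config$snip_iterations)
}
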
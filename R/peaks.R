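#' Robust spectrum noise estimate
#'
#' A single per-spectrum noise scalar: 1.4826 times the median absolute
#' deviation of the (baseline-corrected) intensities, the consistency-scaled
#' MAD that equals the standard deviation for Gaussian data.
#'
#' @param s A processed (baseline-corrected) spectrum, or any spectrum-like
#'   table with an `intensity` column.
#' @return A non-negative scalar in intensity units.
#' @export
estimate_noise_mad <- function(s) {
  y <- s$intensity
  if (length(y) < 3L) abort("Need at least 3 points to estimate noise.")
  stats::mad(y, constant = 1.4826)
}

#' Detect peaks in a processed spectrum
#'
#' A point is called a peak when it is the maximum of the window of
#' `half_window` points on either side and its intensity reaches
#' `snr` times the spectrum's MAD noise ("equal or higher" at the
#' threshold). Ties between equal window maxima keep the lower-mass point.
#' Only points with a full window on both sides are eligible, which keeps
#' baseline-correction residues at the spectrum edges from being called.
#'
#' @param s A processed spectrum.
#' @param snr Signal-to-noise threshold (default 4).
#' @param half_window Window half-width in points (default 40).
#' @param noise Optional externally supplied noise scalar; defaults to
#'   [estimate_noise_mad()] of `s`.
#' @return A tibble of class `peak_list` with columns `mz`, `intensity`,
#'   `snr`, carrying `sample_id`/`replicate`/`noise` attributes.
#' @export
detect_peaks <- function(s, snr = 4, half_window = 40L, noise = NULL) {
  y <- s$intensity
  n <- length(y)
  half_window <- as.integer(half_window)
  if (half_window < 1L) abort("`half_window` must be >= 1.")
  noise <- noise %||% estimate_noise_mad(s)
  thr <- snr * noise
  cand <- which(y >= thr & y > 0)
  cand <- cand[cand > half_window & cand <= n - half_window]
  is_peak <- logical(length(cand))
  for (k in seq_along(cand)) {
    j <- cand[k]
    lo <- j - half_window
    hi <- j + half_window
    left_max <- if (j > lo) max(y[lo:(j - 1L)]) else -Inf
    right_max <- if (j < hi) max(y[(j + 1L):hi]) else -Inf
    # strictly above everything to the left, at least equal to the right:
    # equal-maximum ties resolve to the lower-mass point
    is_peak[k] <- y[j] > left_max && y[j] >= right_max
  }
  idx <- cand[is_peak]
  m <- spectrum_meta(s)
  out <- tibble(mz = s$mz[idx], intensity = y[idx],
                snr = if (noise > 0) y[idx] / noise else rep(Inf, length(idx)))
  structure(out, class = c("peak_list", class(tibble())),
            sample_id = m$sample_id, group = m$group,
            replicate = m$replicate, noise = noise)
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s (replicate %s): %d peaks, noise %.4g\n",
              attr(x, "sample_id"), attr(x, "replicate"), nrow(x),
              attr(x, "noise")))
  invisible(x)
}

#' Bin peaks across spectra into a peak matrix
#'
#' Pooled peak masses from all spectra are partitioned by divisive binning:
#' the sorted mass list is recursively split at its largest gap until every
#' bin satisfies `max |mz - mean(bin)| / mean(bin) <= tolerance` (tolerance
#' is a relative fraction). Each bin's reference mass is the mean of its
#' member masses. If a spectrum contributes several peaks to one bin, its
#' most intense peak is kept. Cells without a peak are 0.
#'
#' @param peak_lists A list of [detect_peaks()] results (at least 2).
#' @param tolerance Maximal relative deviation of a member mass from the bin
#'   mean (default 0.002).
#' @return A tibble of class `peak_matrix`: columns `sample_id`,
#'   `replicate`, then one numeric column per bin (named `mz_<reference>`),
#'   with the numeric reference masses in the `bin_refs` attribute.
#' @export
bin_peaks <- function(peak_lists, tolerance = 0.002) {
  if (tolerance <= 0) abort("`tolerance` must be > 0.")
  if (length(peak_lists) < 2L) abort("Need at least 2 peak lists to bin.")
  ids <- vapply(peak_lists, function(p) attr(p, "sample_id"), "")
  reps <- vapply(peak_lists, function(p) attr(p, "replicate") %||% 1L, 1L)
  pooled <- purrr::map_dfr(seq_along(peak_lists), function(i) {
    p <- peak_lists[[i]]
    if (nrow(p) == 0L) return(tibble(row = integer(), mz = numeric(),
                                     intensity = numeric()))
    tibble(row = i, mz = p$mz, intensity = p$intensity)
  })
  n_rows <- length(peak_lists)
  if (nrow(pooled) == 0L) {
    abort("No peaks in any spectrum; nothing to bin.")
  }
  pooled <- pooled[order(pooled$mz), ]
  bin_id <- divisive_bins(pooled$mz, tolerance)
  pooled$bin <- bin_id
  refs <- vapply(split(pooled$mz, bin_id), mean, 0)
  ord <- order(refs)
  refs <- refs[ord]
  # map original bin labels -> mass-ordered index
  lookup <- setNames(seq_along(refs), names(refs))
  pooled$bin <- lookup[as.character(pooled$bin)]
  vals <- matrix(0, nrow = n_rows, ncol = length(refs))
  for (r in seq_len(nrow(pooled))) {
    i <- pooled$row[r]; j <- pooled$bin[r]
    vals[i, j] <- max(vals[i, j], pooled$intensity[r])
  }
  new_peak_matrix(vals, refs, sample_id = ids, replicate = reps,
                  averaged = FALSE)
}

# split sorted masses at the largest gap until each bin is within tolerance
divisive_bins <- function(mz_sorted, tolerance) {
  n <- length(mz_sorted)
  bins <- integer(n)
  stack <- list(c(1L, n))
  next_id <- 0L
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- rng[1]; hi <- rng[2]
    seg <- mz_sorted[lo:hi]
    m <- mean(seg)
    if (hi == lo || max(abs(seg - m)) / m <= tolerance) {
      next_id <- next_id + 1L
      bins[lo:hi] <- next_id
    } else {
      gaps <- diff(seg)
      cut <- which.max(gaps)          # first largest gap: deterministic
      stack[[length(stack) + 1L]] <- c(lo, lo + cut - 1L)
      stack[[length(stack) + 1L]] <- c(lo + cut, hi)
    }
  }
  bins
}

new_peak_matrix <- function(vals, bin_refs, sample_id, replicate = NULL,
                            averaged = FALSE, binary = FALSE,
                            thresholds = NULL) {
  df <- tibble(sample_id = sample_id)
  if (!averaged) df$replicate <- as.integer(replicate)
  cols <- as_tibble(as.data.frame(vals))
  names(cols) <- bin_colnames(bin_refs)
  df <- dplyr::bind_cols(df, cols)
  structure(df,
            class = c(if (binary) "binary_matrix" else "peak_matrix",
                      class(tibble())),
            bin_refs = as.numeric(bin_refs),
            averaged = averaged,
            thresholds = thresholds)
}

#' Accessors for peak/binary matrices
#'
#' `pm_values()` returns the samples-by-bins numeric matrix (rownames are
#' row keys), `bin_masses()` the numeric reference masses, and
#' `peak_occurrence()` the per-bin fraction of rows in which the peak occurs
#' (value > 0).
#'
#' @param m A `peak_matrix` or `binary_matrix`.
#' @return See each description.
#' @export
pm_values <- function(m) {
  cols <- bin_colnames(attr(m, "bin_refs"))
  v <- as.matrix(as.data.frame(m)[, cols, drop = FALSE])
  rn <- if ("replicate" %in% names(m)) {
    paste(m$sample_id, m$replicate, sep = ":")
  } else m$sample_id
  rownames(v) <- rn
  v
}

#' @rdname pm_values
#' @export
bin_masses <- function(m) attr(m, "bin_refs")

#' @rdname pm_values
#' @export
peak_occurrence <- function(m) {
  v <- pm_values(m)
  tibble(mz = bin_masses(m), occurrence = unname(colMeans(v > 0)))
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d row(s) x %d bin(s)%s\n", nrow(x),
              length(bin_masses(x)),
              if (isTRUE(attr(x, "averaged"))) ", replicate-averaged" else ""))
  invisible(x)
}

#' Average technical replicates of a peak matrix
#'
#' Rows belonging to the same sample are replaced by their arithmetic mean
#' (an absent peak counts as 0). Rows flagged `excluded` in the manifest are
#' dropped before averaging; a sample left with a single replicate passes
#' through unchanged. Averaging an already-averaged matrix is the identity.
#'
#' @param m A `peak_matrix` with `sample_id`/`replicate` rows.
#' @param manifest A `sample_manifest` covering every matrix row.
#' @return A `peak_matrix` with one row per sample.
#' @export
average_replicates <- function(m, manifest) {
  if (isTRUE(attr(m, "averaged"))) return(m)
  key_m <- paste(m$sample_id, m$replicate, sep = "\r")
  key_man <- paste(manifest$sample_id, manifest$replicate, sep = "\r")
  idx <- match(key_m, key_man)
  if (anyNA(idx)) {
    miss <- unique(paste0(m$sample_id, "/", m$replicate)[is.na(idx)])
    abort(sprintf("Matrix row(s) without manifest entry: %s",
                  paste(miss, collapse = ", ")))
  }
  keep <- !manifest$excluded[idx]
  if (!any(keep)) abort("All matrix rows are flagged excluded.")
  v <- pm_values(m)[keep, , drop = FALSE]
  sid <- m$sample_id[keep]
  sums <- rowsum(v, group = sid, reorder = FALSE)
  counts <- as.vector(table(factor(sid, levels = rownames(sums))))
  avg <- sums / counts
  new_peak_matrix(avg, bin_masses(m), sample_id = rownames(sums),
                  averaged = TRUE)
}

#' Drop rarely occurring peaks
#'
#' Bins present (value > 0) in fewer than `min_frac` of the matrix rows are
#' removed; rows are untouched. Raising `min_frac` never adds bins.
#'
#' @param m A `peak_matrix` (typically replicate-averaged).
#' @param min_frac Minimal occurrence fraction; bins with occurrence
#'   strictly below it are dropped (default 0.33).
#' @return The filtered `peak_matrix`.
#' @export
filter_occurrence <- function(m, min_frac = 0.33) {
  if (min_frac < 0 || min_frac > 1) abort("`min_frac` must be in [0, 1].")
  occ <- peak_occurrence(m)$occurrence
  keep <- occ >= min_frac
  if (!any(keep)) {
    abort("All bins fall below `min_frac`; lower the occurrence threshold.")
  }
  v <- pm_values(m)[, keep, drop = FALSE]
  new_peak_matrix(v, bin_masses(m)[keep], sample_id = m$sample_id,
                  replicate = if ("replicate" %in% names(m)) m$replicate,
                  averaged = isTRUE(attr(m, "averaged")))
}
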
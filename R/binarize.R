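#' Dichotomize a peak matrix into presence/absence
#'
#' Each bin gets a single intensity threshold; a cell becomes 1 when its
#' intensity is equal to or higher than the threshold and 0 otherwise. The
#' default threshold is the pooled per-bin mean intensity over all rows,
#' which keeps the binarization label-free and therefore applicable to new
#' samples at prediction time; `method = "classmix"` instead uses the
#' unweighted mean of the per-class means.
#'
#' @param m A `peak_matrix` (replicate-averaged).
#' @param labels Per-row group labels (used for validation, and for the
#'   `"classmix"` threshold). At least two distinct groups are required.
#' @param method `"pooled"` (default) or `"classmix"`.
#' @param thresholds Optional named numeric vector of per-bin thresholds
#'   (names = bin column names), e.g. learned on a training set; when given,
#'   it is applied as-is and `labels` are not consulted.
#' @return A `binary_matrix` with the applied `thresholds` attribute.
#' @export
dichotomize <- function(m, labels = NULL, method = c("pooled", "classmix"),
                        thresholds = NULL) {
  method <- match.arg(method)
  v <- pm_values(m)
  cols <- colnames(v)
  if (is.null(thresholds)) {
    if (is.null(labels)) abort("Provide `labels` (or explicit `thresholds`).")
    if (length(labels) != nrow(v)) abort("One label per matrix row required.")
    if (length(unique(labels)) < 2L) {
      abort("Dichotomization threshold degenerates with a single group; need >= 2 groups.")
    }
    thresholds <- if (method == "pooled") {
      colMeans(v)
    } else {
      class_means <- rowsum(v, group = labels) /
        as.vector(table(factor(labels, levels = unique(labels))))
      colMeans(class_means)
    }
    names(thresholds) <- cols
  } else {
    if (!all(cols %in% names(thresholds))) {
      abort("`thresholds` must cover every bin column of the matrix.")
    }
    thresholds <- thresholds[cols]
  }
  b <- (v >= matrix(thresholds, nrow(v), ncol(v), byrow = TRUE)) * 1
  new_peak_matrix(b, bin_masses(m), sample_id = m$sample_id,
                  replicate = if ("replicate" %in% names(m)) m$replicate,
                  averaged = isTRUE(attr(m, "averaged")),
                  binary = TRUE, thresholds = thresholds)
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("<binary_matrix> %d row(s) x %d bin(s), density %.2f\n",
              nrow(x), length(bin_masses(x)), mean(pm_values(x))))
  invisible(x)
}

#' @rdname pm_values
#' @export
bin_thresholds <- function(m) attr(m, "thresholds")
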
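#' Principal component analysis of a peak or binary matrix
#'
#' Columns are mean-centred (not scaled) and the covariance eigenstructure
#' is extracted via [stats::prcomp()]. The per-component explained variance
#' fraction sums to one over all components.
#'
#' @param m A `peak_matrix`, `binary_matrix`, or plain numeric matrix /
#'   data frame of samples x variables.
#' @return An object of class `pca_result`: list with `scores` (tibble,
#'   one row per sample), `loadings` (variables x components matrix),
#'   `explained_frac`, `sdev`, and the row ids.
#' @export
pca_peaks <- function(m) {
  v <- if (inherits(m, c("peak_matrix", "binary_matrix"))) pm_values(m)
       else as.matrix(m)
  if (nrow(v) < 2L) abort("PCA needs at least 2 rows.")
  if (ncol(v) < 1L) abort("PCA needs at least 1 column.")
  total_var <- sum(apply(v, 2, var))
  if (total_var <= 0) abort("Zero total variance; PCA undefined.")
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(as.data.frame(pc$x))
  scores <- dplyr::bind_cols(tibble(row_id = rownames(v) %||%
                                      as.character(seq_len(nrow(v)))),
                             scores)
  structure(list(scores = scores, loadings = pc$rotation,
                 explained_frac = expl, sdev = pc$sdev,
                 center = pc$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s); PC1+PC2 explain %.1f%% of variance\n",
              length(x$explained_frac),
              100 * sum(x$explained_frac[seq_len(min(2, length(x$explained_frac)))])))
  invisible(x)
}
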
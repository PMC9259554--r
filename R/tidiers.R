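#' Broom-style tidiers
#'
#' `tidy()` returns one row per elementary unit of a result (peak, sample,
#' grid cell); `glance()` a one-row summary.
#'
#' @param x A package result object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.feature_ranking <- function(x, ...) {
  df <- as_tibble(as.data.frame(x))
  tcols <- grep("^t_", names(df), value = TRUE)
  if (length(tcols)) {
    tidyr::pivot_longer(df, dplyr::all_of(tcols), names_to = "group",
                        values_to = "t_score", names_prefix = "t_")
  } else df
}

#' @rdname tidiers
#' @export
glance.feature_ranking <- function(x, ...) {
  tibble(method = attr(x, "method"), n_bins = nrow(x),
         n_significant = sum(x$significant, na.rm = TRUE),
         sig_threshold = attr(x, "sig_threshold"))
}

#' @rdname tidiers
#' @export
tidy.hkmeans_result <- function(x, ...) {
  out <- tibble(row_id = names(x$assignments),
                cluster = unname(x$assignments))
  if (!is.null(x$labels)) out$group <- x$labels
  out
}

#' @rdname tidiers
#' @export
glance.hkmeans_result <- function(x, ...) {
  tibble(k = x$k,
         tot_withinss = x$kmeans$tot.withinss,
         min_homogeneity = if (!is.null(x$homogeneity))
           min(x$homogeneity$homogeneity, na.rm = TRUE) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @rdname tidiers
#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_components = length(x$explained_frac),
         pc1_frac = x$explained_frac[1],
         pc12_frac = sum(x$explained_frac[seq_len(min(2, length(x$explained_frac)))]))
}

#' @rdname tidiers
#' @export
tidy.performance_eval <- function(x, ...) {
  dplyr::bind_rows(dplyr::mutate(x$test, evaluation = "test"),
                   dplyr::mutate(x$cv, evaluation = "cv"))
}

#' @rdname tidiers
#' @export
glance.performance_eval <- function(x, ...) {
  tibble(n_cells = nrow(x$test),
         min_test_accuracy = min(x$test$accuracy),
         max_test_accuracy = max(x$test$accuracy))
}
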
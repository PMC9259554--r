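#' Plot methods
#'
#' Every major result type has an `autoplot()` method returning a ggplot:
#' processed spectra (signal plus estimated baseline), feature rankings
#' (top-score bars), cluster results (PCA score plot with 95% normal
#' confidence ellipses per cluster), PCA scree, and the performance grid.
#'
#' @param object The result to plot.
#' @param ... Passed on where meaningful.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.processed_spectrum <- function(object, ...) {
  df <- tibble(mz = object$mz, intensity = object$intensity,
               baseline = object$baseline)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$intensity), linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), colour = "red",
                       linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Da)", y = "intensity (a.u.)",
                  title = attr(object, "sample_id")) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param top_n How many bins to show (default 20).
#' @export
autoplot.feature_ranking <- function(object, top_n = 20, ...) {
  df <- as_tibble(as.data.frame(object)) |>
    dplyr::arrange(.data$rank) |>
    head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(sprintf("%.1f", .data$mz),
                                                      -.data$rank),
                                   y = .data$aggregate_score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "peak m/z (Da)", y = "aggregate score",
                  title = sprintf("Top %d peaks (%s)", nrow(df),
                                  toupper(attr(object, "method")))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param data A `binary_matrix` (or `peak_matrix`) to project; required
#'   for the cluster score plot.
#' @export
autoplot.hkmeans_result <- function(object, data, ...) {
  pc <- pca_peaks(data)
  df <- pc$scores
  df$cluster <- factor(object$assignments[df$row_id])
  if (!is.null(object$labels)) df$group <- object$labels
  expl <- 100 * pc$explained_frac
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                        colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.95, type = "norm") +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", expl[1]),
                  y = sprintf("PC2 (%.1f%%)", expl[2])) +
    ggplot2::theme_minimal()
  if (!is.null(object$labels)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$group), size = 2)
  }
  p
}

#' @rdname plots
#' @export
autoplot.pca_result <- function(object, ...) {
  df <- tibble(component = seq_along(object$explained_frac),
               explained = 100 * object$explained_frac)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$explained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "% variance explained") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.performance_eval <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity",
                          "ppv", "npv"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$top_k), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(evaluation ~ algorithm) +
    ggplot2::labs(x = "top-k peaks", y = "%") +
    ggplot2::theme_minimal()
}
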
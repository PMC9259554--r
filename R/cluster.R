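#' Asymmetric binary (Jaccard) distance
#'
#' The fraction of positions where exactly one of the two vectors is 1,
#' among positions where at least one is 1. Two all-zero vectors have
#' distance 0 by convention.
#'
#' @param x,y Equal-length 0/1 vectors.
#' @return A dissimilarity in `[0, 1]`.
#' @export
#'
#' @examples
#' binary_distance(c(1, 1, 0), c(1, 0, 0)) # 0.5
binary_distance <- function(x, y) {
  if (length(x) != length(y)) abort("Vectors must have equal length.")
  if (!is_binary_vector(x) || !is_binary_vector(y)) {
    abort("Entries must all be 0 or 1.")
  }
  union <- sum(x == 1 | y == 1)
  if (union == 0) return(0)
  sum(xor(x == 1, y == 1)) / union
}

# full pairwise binary-distance matrix (rows of a 0/1 matrix)
binary_dist_matrix <- function(v) {
  both <- tcrossprod(v)                       # co-presence counts
  ones <- rowSums(v)
  union <- outer(ones, ones, "+") - both
  discord <- union - both
  d <- ifelse(union > 0, discord / union, 0)
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchical k-means clustering on binary fingerprints
#'
#' The binary-distance matrix between rows is clustered agglomeratively
#' with the Ward.D2 criterion; the tree is cut into `k` groups whose
#' within-group mean rows seed a standard (Euclidean) k-means refinement on
#' the raw 0/1 rows. Cluster composition, homogeneity and coverage are
#' computed against the supplied group labels.
#'
#' @param b A `binary_matrix`.
#' @param k Number of clusters (default 3).
#' @param labels Optional per-row group labels for the composition metrics.
#' @return An object of class `hkmeans_result`: a list with `assignments`
#'   (named integer vector), `centers`, `sizes`, `hclust`, `kmeans`, and —
#'   when labels are given — `composition`, `homogeneity`, `coverage`
#'   tibbles (see [composition_metrics()]).
#' @export
hkmeans <- function(b, k = 3L, labels = NULL) {
  v <- pm_values(b)
  if (!all(v %in% c(0, 1))) abort("`b` must be a 0/1 binary matrix.")
  k <- as.integer(k)
  if (k < 1L || k > nrow(v)) abort("`k` must be between 1 and the number of rows.")
  if (ncol(v) < 1L) abort("Need at least one bin.")
  d <- binary_dist_matrix(v)
  hc <- hclust(d, method = "ward.D2")
  cut0 <- cutree(hc, k = k)
  centers <- rowsum(v, group = cut0) /
    as.vector(table(factor(cut0, levels = sort(unique(cut0)))))
  km <- if (k == 1L) {
    list(cluster = rep(1L, nrow(v)), centers = centers,
         size = nrow(v), tot.withinss = sum(sweep(v, 2, centers)^2))
  } else {
    run_kmeans_safe(v, centers)
  }
  assignments <- setNames(as.integer(km$cluster), rownames(v))
  out <- list(assignments = assignments,
              centers = km$centers,
              sizes = as.integer(table(assignments)),
              hclust = hc, kmeans = km, k = k,
              initial_assignments = cut0)
  if (!is.null(labels)) {
    cm <- composition_metrics(assignments, labels)
    out <- c(out, cm)
    out$labels <- as.character(labels)
  }
  structure(out, class = "hkmeans_result")
}

# k-means from given centers; duplicated or degenerate seeds are nudged,
# and an empty cluster is re-seeded at the point farthest from its centre
run_kmeans_safe <- function(v, centers) {
  if (anyDuplicated(round(centers, 12))) {
    dup <- duplicated(round(centers, 12))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(seq_len(sum(dup) * ncol(centers)) * 1e-8,
             nrow = sum(dup))
  }
  tryCatch(
    kmeans(v, centers = centers, iter.max = 100L),
    error = function(e) {
      inform(paste("k-means re-seeding after:", conditionMessage(e)))
      km0 <- kmeans(v, centers = nrow(centers), iter.max = 100L,
                    nstart = 5L)
      km0
    }
  )
}

#' @export
print.hkmeans_result <- function(x, ...) {
  cat(sprintf("<hkmeans_result> k = %d, sizes: %s\n", x$k,
              paste(x$sizes, collapse = ", ")))
  if (!is.null(x$homogeneity)) print(x$homogeneity)
  invisible(x)
}

#' Cluster composition, homogeneity and coverage
#'
#' `homogeneity(cluster)` is the share of the cluster occupied by its
#' dominant group; `coverage(cluster, group)` is the share of the group's
#' rows captured by the cluster. Percentages are also reported rounded
#' half-up to integers, the convention used for published cluster tables.
#'
#' @param assignments Per-row cluster ids.
#' @param labels Per-row group labels, same length.
#' @return A list with `composition` (cluster x group counts, long tibble),
#'   `homogeneity` (per cluster: size, dominant group, percentage) and
#'   `coverage` (per cluster x group percentage). Empty clusters get
#'   `NA` homogeneity.
#' @export
composition_metrics <- function(assignments, labels) {
  if (length(assignments) != length(labels)) {
    abort("`assignments` and `labels` must have equal length.")
  }
  cl <- factor(assignments)
  gr <- factor(as.character(labels))
  tab <- table(cluster = cl, group = gr)
  composition <- as_tibble(tab)
  composition$n <- as.integer(composition$n)
  sizes <- rowSums(tab)
  dom_idx <- apply(tab, 1, which.max)
  homogeneity <- tibble(
    cluster = rownames(tab),
    size = as.integer(sizes),
    dominant_group = colnames(tab)[dom_idx],
    dominant_n = as.integer(tab[cbind(seq_len(nrow(tab)), dom_idx)])
  )
  homogeneity$homogeneity <- ifelse(homogeneity$size > 0,
                                    100 * homogeneity$dominant_n / homogeneity$size,
                                    NA_real_)
  homogeneity$homogeneity_pct <- round_half_up(homogeneity$homogeneity)
  totals <- colSums(tab)
  coverage <- composition
  coverage$group_total <- as.integer(totals[coverage$group])
  coverage$coverage <- 100 * coverage$n / coverage$group_total
  coverage$coverage_pct <- round_half_up(coverage$coverage)
  list(composition = composition, homogeneity = homogeneity,
       coverage = coverage)
}
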
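#' Rank peaks by binary discriminant analysis t-scores
#'
#' For each bin j and group g, with n rows overall, `n_g` in the group,
#' per-group presence frequency `p_gj` and pooled frequency `p_j`, the
#' class-versus-pooled t-score is
#' \deqn{t_{gj} = (\hat p_{gj} - \hat p_j) / \sqrt{\hat p_j (1 - \hat p_j)
#'   (1/n_g - 1/n)}}
#' where the pooled frequency is shrunk into `[eps, 1 - eps]` with
#' `eps = 1/(2n)` to avoid zero variance at degenerate frequencies. A
#' positive t-score marks a peak over-present in that group, a negative one
#' a peak under-present. Bins are ranked by the aggregate score
#' `sum_g t_gj^2` (descending; mass breaks ties), and a bin is flagged
#' significant when any class reaches `|t| >= sig_threshold`.
#'
#' @param b A `binary_matrix`.
#' @param labels Per-row group labels; every group needs >= 2 rows and no
#'   group may contain all rows.
#' @param sig_threshold Absolute t-score cut for the significance flag
#'   (default 2.5, the conventional 95% level for this score).
#' @return A tibble of class `feature_ranking`: columns `bin`, `mz`, one
#'   `t_<group>` column per group, `aggregate_score`, `rank`, `significant`.
#'   The ids of the rows the ranking was computed on travel in the
#'   `row_ids` attribute (leakage guard for supervised evaluation).
#' @export
bda_tscores <- function(b, labels, sig_threshold = 2.5) {
  v <- pm_values(b)
  if (!all(v %in% c(0, 1))) abort("`b` must be a 0/1 binary matrix.")
  labels <- as.character(labels)
  if (length(labels) != nrow(v)) abort("One label per matrix row required.")
  n <- nrow(v)
  groups <- sort(unique(labels))
  n_g <- table(factor(labels, levels = groups))
  if (any(n_g < 2L)) abort("Every group needs at least 2 rows.")
  if (any(n_g == n)) abort("A single group covers all rows; no pooled contrast exists.")
  eps <- 1 / (2 * n)
  p_pool <- pmin(pmax(colMeans(v), eps), 1 - eps)
  tmat <- sapply(groups, function(g) {
    p_g <- colMeans(v[labels == g, , drop = FALSE])
    (p_g - p_pool) / sqrt(p_pool * (1 - p_pool) * (1 / n_g[[g]] - 1 / n))
  })
  tmat <- matrix(tmat, ncol = length(groups),
                 dimnames = list(colnames(v), groups))
  agg <- rowSums(tmat^2)
  mz <- bin_masses(b)
  ord <- order(-agg, mz)
  rk <- integer(length(agg)); rk[ord] <- seq_along(agg)
  out <- tibble(bin = colnames(v), mz = mz)
  for (g in groups) out[[paste0("t_", g)]] <- unname(tmat[, g])
  out$aggregate_score <- unname(agg)
  out$rank <- rk
  out$significant <- unname(apply(abs(tmat), 1, max) >= sig_threshold)
  new_feature_ranking(out, method = "bda", row_ids = rownames(v),
                      sig_threshold = sig_threshold)
}

new_feature_ranking <- function(df, method, row_ids, sig_threshold = NA_real_) {
  structure(df, class = c("feature_ranking", class(tibble())),
            method = method, row_ids = row_ids,
            sig_threshold = sig_threshold)
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %s, %d bins, %d significant\n",
              attr(x, "method"), nrow(x),
              sum(x$significant, na.rm = TRUE)))
  NextMethod()
}

#' Rank peaks by random-forest importance
#'
#' Trains a random forest on all supplied rows and ranks bins by
#' permutation importance (mean decrease in accuracy). Deterministic given
#' `seed`. The per-class t-score columns are absent; `aggregate_score` is
#' the importance.
#'
#' @inheritParams bda_tscores
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return A `feature_ranking` (see [bda_tscores()]).
#' @export
rf_importance_ranking <- function(b, labels, n_trees = 500L, seed = 1L) {
  v <- pm_values(b)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) abort("Need >= 2 groups to rank by importance.")
  fit <- withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = as.data.frame(v),
                               y = factor(labels),
                               ntree = as.integer(n_trees),
                               importance = TRUE))
  imp <- randomForest::importance(fit, type = 1)[, 1]
  imp <- imp[colnames(v)]
  mz <- bin_masses(b)
  ord <- order(-imp, mz)
  rk <- integer(length(imp)); rk[ord] <- seq_along(imp)
  out <- tibble(bin = colnames(v), mz = mz,
                aggregate_score = unname(imp), rank = rk,
                significant = NA)
  new_feature_ranking(out, method = "rf", row_ids = rownames(v))
}

#' Select the top-k ranked bins
#'
#' @param ranking A `feature_ranking`.
#' @param k Number of bins, `1 <= k <= nrow(ranking)`.
#' @return The `k` best-ranked rows, ordered by rank. Top-k sets are nested:
#'   `select_top_k(r, 5)` is always a subset of `select_top_k(r, 10)`.
#' @export
select_top_k <- function(ranking, k) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(ranking)) {
    abort(sprintf("`k` must be between 1 and %d.", nrow(ranking)))
  }
  out <- ranking[order(ranking$rank), ][seq_len(k), ]
  new_feature_ranking(out, method = attr(ranking, "method"),
                      row_ids = attr(ranking, "row_ids"),
                      sig_threshold = attr(ranking, "sig_threshold"))
}

#' Restrict a matrix to the bins of a ranking
#'
#' @param m A `peak_matrix` or `binary_matrix`.
#' @param ranking A `feature_ranking` (e.g. from [select_top_k()]).
#' @return The matrix restricted to the ranking's bins, in ranking order of
#'   mass.
#' @export
select_bins <- function(m, ranking) {
  keep <- match(ranking$bin, bin_colnames(bin_masses(m)))
  if (anyNA(keep)) abort("Ranking refers to bins absent from the matrix.")
  keep <- sort(keep)
  v <- pm_values(m)[, keep, drop = FALSE]
  thr <- attr(m, "thresholds")
  new_peak_matrix(v, bin_masses(m)[keep], sample_id = m$sample_id,
                  replicate = if ("replicate" %in% names(m)) m$replicate,
                  averaged = isTRUE(attr(m, "averaged")),
                  binary = inherits(m, "binary_matrix"),
                  thresholds = if (!is.null(thr)) thr[keep])
}
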
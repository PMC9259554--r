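#' Supervised evaluation grid: algorithms x top-k peak panels
#'
#' Reproduces the canonical evaluation design on a replicate-averaged peak
#' matrix: with a fixed stratified train/test split, each algorithm ranks
#' peaks **on the training rows only**, selects its top-k panel, is
#' assessed by repeated stratified k-fold cross-validation inside the
#' training set, then refitted on the whole training set and scored once on
#' the held-out test set. Binarization thresholds are likewise learned on
#' the training rows and frozen for the test rows.
#'
#' Feature rankings carry the ids of the rows they were computed on; a
#' ranking that has seen any test row is refused (leakage guard).
#'
#' @param pm A replicate-averaged `peak_matrix` (one row per sample).
#' @param manifest A `sample_manifest` providing group labels.
#' @param split A [split_train_test()] result.
#' @param algorithms Subset of `c("bda", "rf")`.
#' @param k_values Peak panel sizes (default `c(5, 10, 15, 20)`).
#' @param cv_folds,cv_repeats Cross-validation design (default 5 x 20).
#' @param seed Master seed; repetition and fold seeds derive from it.
#' @param n_trees Random-forest size (default 500).
#' @param positive_classes Labels collapsed into the positive class for
#'   [compute_metrics()] (default `c("IS", "LPS")`).
#' @param rankings Optional pre-computed named list of `feature_ranking`
#'   objects (names = algorithms); each is checked against the test rows.
#' @return An object of class `performance_eval`: list with `test` and
#'   `cv` tibbles (one row per algorithm x k: accuracy, sensitivity,
#'   specificity, ppv, npv in percent), plus the split.
#' @export
evaluate_grid <- function(pm, manifest, split,
                          algorithms = c("bda", "rf"),
                          k_values = c(5L, 10L, 15L, 20L),
                          cv_folds = 5L, cv_repeats = 20L, seed = 1L,
                          n_trees = 500L,
                          positive_classes = c("IS", "LPS"),
                          rankings = NULL) {
  if (!isTRUE(attr(pm, "averaged"))) {
    abort("`pm` must be replicate-averaged (one row per sample).")
  }
  algorithms <- match.arg(algorithms, c("bda", "rf"), several.ok = TRUE)
  idx_train <- match(split$train_ids, pm$sample_id)
  idx_test <- match(split$test_ids, pm$sample_id)
  if (anyNA(idx_train) || anyNA(idx_test)) {
    abort("Split refers to samples absent from the peak matrix.")
  }
  pm_train <- pm[idx_train, ] |> rebuild_pm(pm)
  pm_test <- pm[idx_test, ] |> rebuild_pm(pm)
  lab_train <- manifest_labels(manifest, split$train_ids)
  lab_test <- manifest_labels(manifest, split$test_ids)
  b_train <- dichotomize(pm_train, lab_train)
  b_test <- dichotomize(pm_test, thresholds = bin_thresholds(b_train))
  test_rows <- list()
  cv_rows <- list()
  for (alg in algorithms) {
    ranking <- rankings[[alg]] %||% switch(alg,
      bda = bda_tscores(b_train, lab_train),
      rf = rf_importance_ranking(b_train, lab_train, n_trees = n_trees,
                                 seed = derive_seed(seed, 1L)))
    assert_no_leakage(ranking, split$test_ids)
    for (k in k_values) {
      if (k > nrow(ranking)) {
        abort(sprintf("k = %d exceeds the %d available bins.", k, nrow(ranking)))
      }
      sel <- select_top_k(ranking, k)
      b_tr <- select_bins(b_train, sel)
      b_te <- select_bins(b_test, sel)
      cv <- cv_metrics(b_tr, lab_train, alg, cv_folds, cv_repeats, seed,
                       n_trees, positive_classes)
      model <- fit_algorithm(alg, b_tr, lab_train, n_trees,
                             derive_seed(seed, 2L))
      pred <- predict(model, b_te)
      met <- compute_metrics(confusion_table(lab_test, pred),
                             positive_classes = positive_classes)
      test_rows[[length(test_rows) + 1L]] <-
        dplyr::bind_cols(tibble(algorithm = toupper(alg), top_k = as.integer(k)), met)
      cv_rows[[length(cv_rows) + 1L]] <-
        dplyr::bind_cols(tibble(algorithm = toupper(alg), top_k = as.integer(k)), cv)
    }
  }
  structure(list(test = dplyr::bind_rows(test_rows),
                 cv = dplyr::bind_rows(cv_rows),
                 split = split,
                 positive_classes = positive_classes),
            class = "performance_eval")
}

rebuild_pm <- function(sub, parent) {
  new_peak_matrix(as.matrix(as.data.frame(sub)[, bin_colnames(bin_masses(parent)),
                                               drop = FALSE]),
                  bin_masses(parent), sample_id = sub$sample_id,
                  averaged = TRUE)
}

assert_no_leakage <- function(ranking, test_ids) {
  seen <- attr(ranking, "row_ids")
  if (is.null(seen)) abort("Ranking carries no row ids; cannot verify leakage.")
  overlap <- intersect(seen, test_ids)
  if (length(overlap)) {
    abort(sprintf(
      "Refusing ranking computed on rows overlapping the test set (%d overlapping sample(s)).",
      length(overlap)))
  }
  invisible(TRUE)
}

fit_algorithm <- function(alg, b, labels, n_trees, seed) {
  switch(alg,
         bda = train_bda_classifier(b, labels),
         rf = train_rf_classifier(b, labels, n_trees = n_trees, seed = seed))
}

# repeated stratified k-fold CV inside the training rows; per repetition the
# fold confusions are pooled, metrics computed, then averaged over repetitions
cv_metrics <- function(b, labels, alg, cv_folds, cv_repeats, seed, n_trees,
                       positive_classes) {
  v_rows <- seq_len(nrow(b))
  reps <- lapply(seq_len(cv_repeats), function(rep) {
    folds <- stratified_folds(labels, cv_folds, derive_seed(seed, 10L + rep))
    truth <- character(0); pred <- character(0)
    for (f in seq_len(cv_folds)) {
      hold <- v_rows[folds == f]
      keep <- v_rows[folds != f]
      if (length(unique(labels[keep])) < 2L || length(hold) == 0L) next
      model <- fit_algorithm(alg, subset_binary(b, keep), labels[keep],
                             n_trees, derive_seed(seed, 1000L + rep * 10L + f))
      pred <- c(pred, predict(model, subset_binary(b, hold)))
      truth <- c(truth, labels[hold])
    }
    compute_metrics(confusion_table(truth, pred),
                    positive_classes = positive_classes)
  })
  agg <- dplyr::bind_rows(reps)
  dplyr::summarise(agg, dplyr::across(dplyr::everything(),
                                      ~ round_half_up(mean(.x, na.rm = TRUE), 1)))
}

stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      idx <- sample(idx)
      folds[idx] <- rep_len(sample(k), length(idx))
    }
  })
  folds
}

subset_binary <- function(b, rows) {
  v <- pm_values(b)[rows, , drop = FALSE]
  new_peak_matrix(v, bin_masses(b), sample_id = b$sample_id[rows],
                  averaged = TRUE, binary = TRUE,
                  thresholds = attr(b, "thresholds"))
}

#' @export
print.performance_eval <- function(x, ...) {
  cat("<performance_eval> held-out test metrics:\n")
  print(x$test)
  cat("cross-validation means (training set):\n")
  print(x$cv)
  invisible(x)
}

#' No-information rate of a test split
#'
#' Accuracy of always predicting the majority side of the collapsed
#' binary problem; the reference point for permutation-null checks.
#'
#' @param labels Test-set labels.
#' @param positive_classes Labels forming the positive class.
#' @return Percentage in `[0, 100]`.
#' @export
no_information_rate <- function(labels, positive_classes = c("IS", "LPS")) {
  p <- mean(labels %in% positive_classes)
  100 * max(p, 1 - p)
}
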
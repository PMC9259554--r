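#' Stratified train/test split at the sample level
#'
#' Samples (not individual replicates) are split group by group, so both
#' replicates of a sample always land on the same side. The per-group
#' training count is `round(train_frac * n_g)` (half-up), keeping every
#' group's train fraction within one sample of the global fraction.
#' Deterministic given `seed`.
#'
#' @param manifest A `sample_manifest` (excluded replicates are ignored;
#'   a sample is eligible while it retains any replicate).
#' @param train_frac Training fraction in (0, 1), default 0.6.
#' @param seed Integer seed.
#' @return An object of class `split_spec`: list with `train_ids`,
#'   `test_ids`, `seed`, `stratified = TRUE`.
#' @export
split_train_test <- function(manifest, train_frac = 0.6, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must lie strictly between 0 and 1.")
  }
  active <- manifest[!manifest$excluded, , drop = FALSE]
  samples <- unique(tibble(sample_id = active$sample_id, group = active$group))
  counts <- table(samples$group)
  if (any(counts < 2L)) abort("Every group needs at least 2 samples to split.")
  pieces <- withr::with_seed(as.integer(seed), {
    lapply(sort(unique(samples$group)), function(g) {
      ids <- samples$sample_id[samples$group == g]
      n_train <- as.integer(round_half_up(train_frac * length(ids)))
      if (n_train < 1L || n_train >= length(ids)) {
        abort(sprintf("`train_frac` leaves group '%s' empty on one side.", g))
      }
      tr <- sample(ids, n_train)
      list(train = tr, test = setdiff(ids, tr))
    })
  })
  structure(list(train_ids = unlist(lapply(pieces, `[[`, "train")),
                 test_ids = unlist(lapply(pieces, `[[`, "test")),
                 seed = as.integer(seed), stratified = TRUE),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test samples (seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Confusion table from truth and predictions
#'
#' @param truth,predicted Equal-length label vectors; rows of the table are
#'   truth, columns predictions, over the union of observed labels.
#' @return A square contingency table.
#' @export
confusion_table <- function(truth, predicted) {
  lv <- sort(unique(c(as.character(truth), as.character(predicted))))
  table(truth = factor(truth, levels = lv),
        predicted = factor(predicted, levels = lv))
}

#' Binary-collapse performance metrics
#'
#' A multi-class confusion table is collapsed to positive-versus-negative:
#' the positive class is the union of `positive_classes` (by default every
#' non-control state, `{IS, LPS}`, against `CTL`). Any call inside the
#' positive union counts as a true positive. Accuracy, sensitivity,
#' specificity, PPV and NPV are returned in percent at one decimal
#' (half-up); a metric with a zero denominator is `NA`, never 0.
#' `mode = "macro"` instead macro-averages one-vs-rest metrics over all
#' classes.
#'
#' @param confusion A square truth x predicted table ([confusion_table()]).
#' @param positive_classes Labels forming the positive class; must be a
#'   proper non-empty subset of the table's classes (ignored for
#'   `mode = "macro"`).
#' @param mode `"binary"` (default) or `"macro"`.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` (percent).
#' @export
compute_metrics <- function(confusion, positive_classes = c("IS", "LPS"),
                            mode = c("binary", "macro")) {
  mode <- match.arg(mode)
  if (sum(confusion) == 0) abort("Empty confusion table.")
  classes <- rownames(confusion)
  if (mode == "macro") {
    per <- lapply(classes, function(g) binary_metrics(collapse_confusion(confusion, g)))
    out <- purrr::map_dfr(per, identity)
    return(tibble(accuracy = mean(out$accuracy), sensitivity = mean(out$sensitivity),
                  specificity = mean(out$specificity), ppv = mean(out$ppv),
                  npv = mean(out$npv)))
  }
  positive_classes <- intersect(positive_classes, classes)
  if (length(positive_classes) == 0L || length(positive_classes) == length(classes)) {
    abort("`positive_classes` must be a proper non-empty subset of the observed classes.")
  }
  binary_metrics(collapse_confusion(confusion, positive_classes))
}

# collapse a k-class confusion table to (TP, FN, FP, TN)
collapse_confusion <- function(confusion, positive_classes) {
  pos <- rownames(confusion) %in% positive_classes
  c(tp = sum(confusion[pos, pos, drop = FALSE]),
    fn = sum(confusion[pos, !pos, drop = FALSE]),
    fp = sum(confusion[!pos, pos, drop = FALSE]),
    tn = sum(confusion[!pos, !pos, drop = FALSE]))
}

binary_metrics <- function(cts) {
  rate <- function(num, den) {
    if (den > 0) unname(round_half_up(100 * num / den, 1)) else NA_real_
  }
  tibble(
    accuracy = rate(cts["tp"] + cts["tn"], sum(cts)),
    sensitivity = rate(cts["tp"], cts["tp"] + cts["fn"]),
    specificity = rate(cts["tn"], cts["tn"] + cts["fp"]),
    ppv = rate(cts["tp"], cts["tp"] + cts["fp"]),
    npv = rate(cts["tn"], cts["tn"] + cts["fn"])
  )
}

#' Bernoulli discriminant classifier on binary fingerprints
#'
#' Per class g and bin j the model stores the Laplace-smoothed presence
#' frequency `q_gj = (count_gj + 1) / (n_g + 2)` and the class prior
#' `pi_g = n_g / n`. A sample `x` is scored by the Bernoulli log-likelihood
#' `log pi_g + sum_j [x_j log q_gj + (1 - x_j) log(1 - q_gj)]` and assigned
#' to the arg-max class; exact score ties go to the lexicographically first
#' label. The model is bound to the bin set (and binarization thresholds)
#' it was trained on and refuses prediction on anything else.
#'
#' @param b A training `binary_matrix`.
#' @param labels Per-row class labels (>= 2 classes).
#' @return An object of class `bda_classifier`.
#' @export
train_bda_classifier <- function(b, labels) {
  v <- pm_values(b)
  if (!all(v %in% c(0, 1))) abort("`b` must be a 0/1 binary matrix.")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) abort("Need >= 2 classes to train.")
  n <- nrow(v)
  q <- sapply(classes, function(g) {
    rows <- labels == g
    (colSums(v[rows, , drop = FALSE]) + 1) / (sum(rows) + 2)
  })
  q <- matrix(q, ncol = length(classes),
              dimnames = list(colnames(v), classes))
  prior <- as.vector(table(factor(labels, levels = classes))) / n
  structure(list(classes = classes, log_q = log(q), log_1mq = log(1 - q),
                 log_prior = log(prior), bins = colnames(v),
                 thresholds = attr(b, "thresholds")),
            class = "bda_classifier")
}

#' @export
predict.bda_classifier <- function(object, newdata, type = c("class", "score"),
                                   ...) {
  type <- match.arg(type)
  v <- if (inherits(newdata, c("binary_matrix", "peak_matrix"))) {
    pm_values(newdata)
  } else as.matrix(newdata)
  if (!identical(colnames(v), object$bins)) {
    if (!all(object$bins %in% colnames(v))) {
      abort("Prediction data lack bins the model was trained on.")
    }
    v <- v[, object$bins, drop = FALSE]
  }
  if (!all(v %in% c(0, 1))) abort("Prediction data must be binary (0/1).")
  scores <- v %*% object$log_q + (1 - v) %*% object$log_1mq
  scores <- sweep(scores, 2, object$log_prior, "+")
  if (type == "score") return(scores)
  # classes are lexicographically sorted, so which.max resolves ties to
  # the first label
  object$classes[apply(scores, 1, which.max)]
}

#' Random-forest classifier wrapper
#'
#' Bootstrap-aggregated trees on the binary features via the
#' `randomForest` package, with seeded determinism and majority-vote
#' prediction owned by this wrapper.
#'
#' @inheritParams train_bda_classifier
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return An object of class `rf_classifier`.
#' @export
train_rf_classifier <- function(b, labels, n_trees = 500L, seed = 1L) {
  if (n_trees < 1L) abort("`n_trees` must be >= 1.")
  v <- pm_values(b)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) abort("Need >= 2 classes to train.")
  fit <- withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = as.data.frame(v), y = factor(labels),
                               ntree = as.integer(n_trees)))
  structure(list(fit = fit, bins = colnames(v),
                 thresholds = attr(b, "thresholds"), seed = as.integer(seed)),
            class = "rf_classifier")
}

#' @export
predict.rf_classifier <- function(object, newdata, ...) {
  v <- if (inherits(newdata, c("binary_matrix", "peak_matrix"))) {
    pm_values(newdata)
  } else as.matrix(newdata)
  if (!all(object$bins %in% colnames(v))) {
    abort("Prediction data lack bins the model was trained on.")
  }
  v <- v[, object$bins, drop = FALSE]
  as.character(predict(object$fit, as.data.frame(v)))
}
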
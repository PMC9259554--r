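test_that("stratified sample-level split hits per-group counts and is seed-deterministic", {
  man <- validate_manifest(tibble::tibble(
    sample_id = rep(sprintf("s%03d", 1:76), each = 2),
    group = rep(c(rep("CTL", 25), rep("IS", 22), rep("LPS", 29)), each = 2),
    replicate = rep(1:2, 76)))
  sp <- split_train_test(man, train_frac = 0.6, seed = 11)
  tr_groups <- table(man$group[match(sp$train_ids, man$sample_id)])
  expect_equal(as.vector(tr_groups[c("CTL", "IS", "LPS")]), c(15, 13, 17))
  expect_equal(length(sp$test_ids), 76 - 45)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)

  sp2 <- split_train_test(man, train_frac = 0.6, seed = 11)
  expect_identical(sort(sp2$train_ids), sort(sp$train_ids))

  man6 <- validate_manifest(tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("A", "B", "C"), each = 2), replicate = 1L))
  sp3 <- split_train_test(man6, train_frac = 0.5, seed = 1)
  tr3 <- table(man6$group[match(sp3$train_ids, man6$sample_id)])
  expect_equal(as.vector(tr3), c(1, 1, 1))
})

test_that("Bernoulli discriminant scores equal an independent log-likelihood summation", {
  v <- cbind(c(1, 1, 0, 0), c(1, 0, 0, 1))
  b <- make_matrix(v, refs = c(3000, 4000))
  labels <- c("A", "A", "B", "B")
  fit <- train_bda_classifier(b, labels)
  x <- c(1, 0)
  # hand summation: q_gA = ((2+1)/4, (1+1)/4), q_gB = ((0+1)/4, (1+1)/4)
  sA <- log(0.5) + log(3 / 4) + log(1 - 2 / 4)
  sB <- log(0.5) + log(1 / 4) + log(1 - 2 / 4)
  sc <- predict(fit, matrix(x, 1, 2, dimnames = list(NULL, fit$bins)),
                type = "score")
  expect_equal(unname(sc[1, ]), c(sA, sB), tolerance = 1e-12)

  # separable training: presence on the marker peak predicts its class
  v2 <- cbind(c(1, 1, 1, 0, 0, 0), rep(c(0, 1), 3))
  b2 <- make_matrix(v2, refs = c(3000, 4000))
  fit2 <- train_bda_classifier(b2, rep(c("A", "B"), each = 3))
  test2 <- make_matrix(rbind(c(1, 0), c(0, 1)), refs = c(3000, 4000),
                       sample_id = c("t1", "t2"))
  expect_equal(predict(fit2, test2), c("A", "B"))

  # uninformative peaks: the prior carries the prediction
  v3 <- matrix(rep(c(0, 1), 6), 6, 2)
  b3 <- make_matrix(v3, refs = c(3000, 4000))
  fit3 <- train_bda_classifier(b3, c(rep("A", 4), rep("B", 2)))
  expect_equal(unique(predict(fit3, b3)), "A")

  # exact ties go to the lexicographically first label
  v4 <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  fitT <- train_bda_classifier(make_matrix(v4, refs = c(3000, 4000)),
                               c("B", "B", "A", "A"))
  scT <- predict(fitT, make_matrix(rbind(c(1, 1)), refs = c(3000, 4000),
                                   sample_id = "t"), type = "score")
  expect_equal(scT[1, "A"], scT[1, "B"], tolerance = 1e-12)
  expect_equal(predict(fitT, make_matrix(rbind(c(1, 1)),
                                         refs = c(3000, 4000),
                                         sample_id = "t")), "A")

  expect_error(predict(fit2, make_matrix(cbind(c(1, 0)), refs = 9000,
                                         sample_id = c("t1", "t2"))),
               "lack bins")
})

test_that("random-forest wrapper is deterministic, separates separable data, and is null on noise", {
  v <- cbind(c(rep(1, 8), rep(0, 8)),
             withr::with_seed(3, matrix(rbinom(64, 1, 0.5), 16, 4)))
  b <- make_matrix(v, refs = seq(3000, by = 500, length.out = 5))
  labels <- rep(c("pos", "neg"), each = 8)
  f1 <- train_rf_classifier(b, labels, n_trees = 200, seed = 4)
  f2 <- train_rf_classifier(b, labels, n_trees = 200, seed = 4)
  expect_identical(predict(f1, b), predict(f2, b))
  expect_equal(predict(f1, b), labels)

  # pure noise, balanced classes: held-out accuracy is near 50%
  vn <- withr::with_seed(9, matrix(rbinom(200 * 6, 1, 0.5), 200, 6))
  bn <- make_matrix(vn, refs = seq(3000, by = 400, length.out = 6))
  ln <- rep(c("a", "b"), 100)
  train <- seq_len(100); test <- 101:200
  fn <- train_rf_classifier(plasmapeaks:::subset_binary(bn, train),
                            ln[train], n_trees = 300, seed = 12)
  acc <- mean(predict(fn, plasmapeaks:::subset_binary(bn, test)) == ln[test])
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)

  expect_error(train_rf_classifier(b, labels, n_trees = 0), ">= 1")
})

test_that("binary-collapse metrics reproduce published-style arithmetic and identities", {
  # perfect table
  perfect <- confusion_table(rep(c("CTL", "IS", "LPS"), c(5, 5, 5)),
                             rep(c("CTL", "IS", "LPS"), c(5, 5, 5)))
  expect_equal(unlist(compute_metrics(perfect)),
               c(accuracy = 100, sensitivity = 100, specificity = 100,
                 ppv = 100, npv = 100))

  # TP=22 FN=1 TN=10 FP=1 with 11 CTL / 9 IS / 14 LPS test labels
  truth <- c(rep("CTL", 11), rep("IS", 9), rep("LPS", 14))
  pred <- c(rep("CTL", 10), "IS",            # 1 control called positive
            rep("IS", 9),                    # IS all called positive
            "CTL", rep("LPS", 13))           # 1 LPS called control
  met <- compute_metrics(confusion_table(truth, pred))
  expect_equal(unlist(met),
               c(accuracy = 94.1, sensitivity = 95.7, specificity = 90.9,
                 ppv = 95.7, npv = 90.9))

  # swapping the positive role swaps S<->E and PPV<->NPV
  met_sw <- compute_metrics(confusion_table(truth, pred),
                            positive_classes = "CTL")
  expect_equal(met_sw$sensitivity, met$specificity)
  expect_equal(met_sw$specificity, met$sensitivity)
  expect_equal(met_sw$ppv, met$npv)
  expect_equal(met_sw$npv, met$ppv)

  # accuracy lies between prevalence-weighted S and E bounds
  expect_gte(met$accuracy, min(met$sensitivity, met$specificity))
  expect_lte(met$accuracy, max(met$sensitivity, met$specificity))

  # zero denominator reports NA, not 0
  t2 <- confusion_table(c("CTL", "CTL"), c("CTL", "CTL"))
  expect_error(compute_metrics(t2), "proper non-empty subset")
  t3 <- confusion_table(c("CTL", "IS"), c("CTL", "CTL"))
  m3 <- compute_metrics(t3, positive_classes = "IS")
  expect_true(is.na(m3$ppv))

  # macro mode averages one-vs-rest metrics
  mm <- compute_metrics(perfect, mode = "macro")
  expect_equal(mm$accuracy, 100)
})

test_that("evaluation grid has the algorithms-by-k shape and a structural leakage guard", {
  sp <- small_pipeline()
  man <- sp$ds$manifest
  split <- split_train_test(man, train_frac = 0.6, seed = 5)
  perf <- evaluate_grid(sp$pm, man, split, k_values = c(5L, 10L, 15L, 20L),
                        cv_folds = 3L, cv_repeats = 2L, seed = 5)
  expect_equal(nrow(perf$test), 8)
  expect_equal(nrow(perf$cv), 8)
  expect_setequal(unique(perf$test$algorithm), c("BDA", "RF"))
  expect_equal(sort(unique(perf$test$top_k)), c(5L, 10L, 15L, 20L))
  expect_true(all(perf$test$accuracy >= 0 & perf$test$accuracy <= 100))

  # a ranking that saw the whole dataset (including test rows) is refused
  leaky <- bda_tscores(sp$binary, sp$labels)
  expect_error(
    evaluate_grid(sp$pm, man, split, algorithms = "bda",
                  k_values = 5L, cv_folds = 3L, cv_repeats = 1L, seed = 5,
                  rankings = list(bda = leaky)),
    "overlapping the test set")
})
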
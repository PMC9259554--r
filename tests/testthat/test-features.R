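# literal re-evaluation of the class-vs-pooled Bernoulli t-score
tscore_oracle <- function(v, labels) {
  n <- nrow(v); eps <- 1 / (2 * n)
  groups <- sort(unique(labels))
  sapply(groups, function(g) {
    vapply(seq_len(ncol(v)), function(j) {
      p <- mean(v[, j]); p <- min(max(p, eps), 1 - eps)
      pg <- mean(v[labels == g, j])
      ng <- sum(labels == g)
      (pg - p) / sqrt(p * (1 - p) * (1 / ng - 1 / n))
    }, 0)
  })
}

test_that("dichotomization thresholds at the pooled mean with the equal-or-higher rule", {
  m <- make_matrix(cbind(c(0, 0, 10, 10), c(7, 7, 7, 7)), binary = FALSE)
  b <- dichotomize(m, labels = c("A", "A", "B", "B"))
  v <- pm_values(b)
  expect_equal(unname(v[, 1]), c(0, 0, 1, 1))       # threshold 5
  expect_equal(unname(v[, 2]), c(1, 1, 1, 1))       # constant bin: all >= mean
  expect_equal(unname(bin_thresholds(b)), c(5, 7))

  # random matrix: independent pass reproduces every cell
  vr <- withr::with_seed(31, matrix(runif(60, 0, 10), 12, 5))
  mr <- make_matrix(vr, refs = seq(2500, by = 700, length.out = 5),
                    binary = FALSE)
  br <- dichotomize(mr, labels = rep(c("A", "B", "C"), each = 4))
  manual <- sweep(vr, 2, colMeans(vr), ">=") * 1
  expect_equal(unname(pm_values(br)), unname(manual))

  expect_error(dichotomize(m, labels = rep("A", 4)), "single group")
})

test_that("BDA t-scores equal the hand-computed toy and keep the sign convention", {
  v <- cbind(c(1, 1, 0, 0, 0, 0),
             c(1, 0, 1, 0, 1, 0),
             c(1, 1, 1, 1, 0, 0))
  b <- make_matrix(v, refs = c(3000, 4000, 5000))
  labels <- c("A", "A", "B", "B", "C", "C")
  rk <- bda_tscores(b, labels)
  # frozen values from the closed form: peak 1 gives t_A = sqrt(6),
  # t_B = t_C = -sqrt(3/2); peak 2 is frequency-balanced (all zero);
  # peak 3 mirrors peak 1 with C depleted
  expect_equal(rk$t_A, c(sqrt(6), 0, sqrt(3 / 2)), tolerance = 1e-12)
  expect_equal(rk$t_B, c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-12)
  expect_equal(rk$t_C, c(-sqrt(3 / 2), 0, -sqrt(6)), tolerance = 1e-12)
  expect_equal(rk$aggregate_score, c(9, 0, 9), tolerance = 1e-12)
  expect_equal(rk$rank, c(1L, 3L, 2L))    # aggregate tie broken by mass
  expect_equal(rk$significant, c(FALSE, FALSE, FALSE))  # max |t| < 2.5

  # oracle equivalence on a random binary matrix
  vr <- withr::with_seed(17, matrix(rbinom(120, 1, 0.4), 12, 10))
  br <- make_matrix(vr, refs = seq(2500, by = 300, length.out = 10))
  lr <- rep(c("A", "B", "C"), each = 4)
  rr <- bda_tscores(br, lr)
  expect_equal(unname(cbind(rr$t_A, rr$t_B, rr$t_C)),
               unname(tscore_oracle(vr, lr)), tolerance = 1e-10)

  # separable peak: positive in its group, negative elsewhere, ranked first
  v2 <- withr::with_seed(23, cbind(c(rep(1, 4), rep(0, 8)),
                                   matrix(rbinom(48, 1, 0.5), 12, 4)))
  b2 <- make_matrix(v2, refs = seq(2500, by = 400, length.out = 5))
  rk2 <- bda_tscores(b2, rep(c("A", "B", "C"), each = 4))
  expect_gt(rk2$t_A[1], 0)
  expect_lt(rk2$t_B[1], 0)
  expect_lt(rk2$t_C[1], 0)
  expect_equal(rk2$rank[1], 1L)
  expect_true(rk2$significant[1])

  expect_error(bda_tscores(b, rep(c("A", "B"), c(1, 5))), "at least 2 rows")
})

test_that("per-bin weighted deviations from the pooled frequency cancel", {
  vr <- withr::with_seed(41, matrix(rbinom(200, 1, 0.3), 20, 10))
  labels <- rep(c("A", "B", "C", "D"), each = 5)
  p_pool <- colMeans(vr)
  s <- rep(0, ncol(vr))
  for (g in unique(labels)) {
    ng <- sum(labels == g)
    s <- s + ng * (colMeans(vr[labels == g, ]) - p_pool)
  }
  expect_equal(s, rep(0, ncol(vr)), tolerance = 1e-12)
})

test_that("binarized rankings are invariant to per-bin monotone rescaling", {
  sp <- small_pipeline()
  v <- pm_values(sp$pm)
  scales <- withr::with_seed(5, runif(ncol(v), 0.2, 8))
  v2 <- sweep(v, 2, scales, "*")
  m2 <- make_matrix(v2, refs = bin_masses(sp$pm),
                    sample_id = sp$pm$sample_id, binary = FALSE)
  rk1 <- bda_tscores(dichotomize(sp$pm, sp$labels), sp$labels)
  rk2 <- bda_tscores(dichotomize(m2, sp$labels), sp$labels)
  expect_equal(rk2$rank, rk1$rank)
  expect_equal(rk2$aggregate_score, rk1$aggregate_score, tolerance = 1e-9)
})

test_that("top-k selection is range-checked, order-preserving and nested", {
  sp <- small_pipeline()
  rk <- bda_tscores(sp$binary, sp$labels)
  expect_equal(nrow(select_top_k(rk, nrow(rk))), nrow(rk))
  expect_error(select_top_k(rk, 0), "between 1")
  expect_error(select_top_k(rk, nrow(rk) + 1), "between 1")
  tops <- lapply(c(5, 10, 15, 20), function(k) select_top_k(rk, k)$bin)
  for (i in 1:3) expect_true(all(tops[[i]] %in% tops[[i + 1]]))
  expect_equal(select_top_k(rk, 5)$rank, 1:5)
})

test_that("random-forest importance ranking is seeded-deterministic and finds a separating peak", {
  v <- withr::with_seed(13, cbind(c(rep(1, 6), rep(0, 12)),
                                  matrix(rbinom(18 * 6, 1, 0.5), 18, 6)))
  b <- make_matrix(v, refs = seq(2500, by = 350, length.out = 7))
  labels <- rep(c("A", "B", "C"), each = 6)
  r1 <- rf_importance_ranking(b, labels, n_trees = 300, seed = 99)
  r2 <- rf_importance_ranking(b, labels, n_trees = 300, seed = 99)
  expect_equal(r1$rank, r2$rank)
  expect_equal(r1$aggregate_score, r2$aggregate_score)
  expect_equal(r1$rank[1], 1L)
})

test_that("BDA and RF top panels overlap substantially on simulated signatures", {
  sp <- small_pipeline()
  rk_bda <- select_top_k(bda_tscores(sp$binary, sp$labels), 20)
  rk_rf <- select_top_k(rf_importance_ranking(sp$binary, sp$labels,
                                              seed = 7), 20)
  expect_gte(length(intersect(rk_bda$bin, rk_rf$bin)), 10)
})

test_that("label permutation leaves few peaks above the significance cut", {
  sp <- small_pipeline()
  fracs <- vapply(1:5, function(i) {
    perm <- withr::with_seed(500 + i, sample(sp$labels))
    rk <- bda_tscores(sp$binary, perm)
    mean(rk$significant)
  }, 0)
  expect_lte(mean(fracs), 0.10)
})
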
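# brute-force window scan used as the peak-detection oracle
detect_oracle <- function(y, snr, noise, hw) {
  thr <- snr * noise
  out <- integer(0)
  for (j in seq_along(y)) {
    if (y[j] < thr || y[j] <= 0) next
    if (j <= hw || j > length(y) - hw) next    # needs a full window
    left <- y[(j - hw):(j - 1)]
    right <- y[(j + 1):(j + hw)]
    if (y[j] > max(left) && y[j] >= max(right)) out <- c(out, j)
  }
  out
}

test_that("MAD noise matches its definition, is robust, and is Gaussian-consistent", {
  s <- raw_spectrum(seq(2000, length.out = 10), rep(4, 10))
  expect_equal(estimate_noise_mad(s), 0)

  spike <- raw_spectrum(seq(2000, length.out = 5), c(1, 1, 1, 1, 100))
  expect_equal(estimate_noise_mad(spike), 0)

  y <- abs(withr::with_seed(2, rnorm(10000, 50, 1)))
  g <- raw_spectrum(seq(2000, length.out = 10000), y)
  expect_equal(estimate_noise_mad(g), 1, tolerance = 0.05)

  # definition check against a literal computation
  y2 <- withr::with_seed(4, runif(101, 0, 7))
  s2 <- raw_spectrum(seq(2000, length.out = 101), y2)
  expect_equal(estimate_noise_mad(s2),
               1.4826 * median(abs(y2 - median(y2))))
  expect_error(estimate_noise_mad(raw_spectrum(c(2000, 2001), c(1, 2))),
               "at least 3")
})

test_that("peak detection matches a brute-force window scan and honours the SNR boundary", {
  # flat zero spectrum: nothing to report
  z <- raw_spectrum(seq(2000, length.out = 200), rep(0, 200))
  expect_equal(nrow(detect_peaks(z)), 0)

  # three planted Gaussians well above noise, spaced > 2 x half-window
  x <- seq_len(2000)
  apexes <- c(400, 1000, 1600)
  y <- withr::with_seed(9, abs(rnorm(2000, 0, 1)))
  noise <- estimate_noise_mad(raw_spectrum(seq(2000, length.out = 2000), y))
  for (a in apexes) y <- y + 10 * noise * exp(-(x - a)^2 / (2 * 3^2))
  s <- raw_spectrum(seq(2000, length.out = 2000), y)
  pk <- detect_peaks(s, snr = 4, half_window = 40)
  oracle_idx <- detect_oracle(s$intensity, 4, estimate_noise_mad(s), 40)
  expect_equal(match(pk$mz, s$mz), oracle_idx)
  big <- pk$mz[pk$snr > 6]
  # noise can shift an apex by one grid point
  expect_true(all(abs(sort(match(big, s$mz)) - apexes) <= 1))

  # "equal or higher" threshold convention at the SNR boundary
  base <- rep(c(0, 2, 0, -2), 250)           # MAD-stable sawtooth
  base <- abs(base) + 1
  sb <- raw_spectrum(seq(2000, length.out = 1000), base)
  nz <- estimate_noise_mad(sb)
  expect_gt(nz, 0)
  y1 <- base; y1[500] <- 3.9 * nz
  y2 <- base; y2[500] <- 4.0 * nz
  hit <- function(y) 2499 %in% round(detect_peaks(
    raw_spectrum(seq(2000, length.out = 1000), y),
    snr = 4, half_window = 10, noise = nz)$mz)
  expect_false(hit(y1))
  expect_true(hit(y2))
})

test_that("divisive binning merges within tolerance, splits across it, and recovers a jittered template", {
  # two spectra, peaks 0.5 Da apart with covering tolerance -> one bin
  pls <- list(make_peak_list(5000.0, 4, "a"), make_peak_list(5000.5, 6, "b"))
  m <- bin_peaks(pls, tolerance = 1e-4)
  expect_equal(bin_masses(m), 5000.25)
  expect_equal(unname(pm_values(m)[, 1]), c(4, 6))

  # far-apart peaks with small tolerance -> two bins, each occurrence 0.5
  pls2 <- list(make_peak_list(3000, 5, "a"), make_peak_list(9000, 5, "b"))
  m2 <- bin_peaks(pls2, tolerance = 1e-4)
  expect_equal(bin_masses(m2), c(3000, 9000))
  expect_equal(peak_occurrence(m2)$occurrence, c(0.5, 0.5))

  # 20 spectra of a jittered 10-peak template -> exactly 10 full bins
  template <- seq(2500, 16000, length.out = 10)
  jit <- withr::with_seed(21, lapply(1:20, function(i)
    make_peak_list(template + rnorm(10, 0, 0.05), sample_id = paste0("s", i))))
  m3 <- bin_peaks(jit, tolerance = 0.002)
  expect_equal(length(bin_masses(m3)), 10)
  expect_equal(peak_occurrence(m3)$occurrence, rep(1, 10))
  expect_equal(bin_masses(m3), template, tolerance = 1e-3)

  # same spectrum contributing twice to a bin keeps its most intense peak
  pls3 <- list(make_peak_list(c(5000.0, 5000.4), c(2, 7), "a"),
               make_peak_list(5000.2, 5, "b"))
  m4 <- bin_peaks(pls3, tolerance = 1e-3)
  expect_equal(length(bin_masses(m4)), 1)
  expect_equal(unname(pm_values(m4)[, 1]), c(7, 5))

  expect_error(bin_peaks(pls, tolerance = 0), "tolerance")
})

test_that("binning is invariant to the input order of peak lists", {
  sp <- small_pipeline()
  pls <- sp$stage$peak_lists
  m_fwd <- bin_peaks(pls, tolerance = 0.002)
  m_rev <- bin_peaks(rev(pls), tolerance = 0.002)
  expect_equal(bin_masses(m_rev), bin_masses(m_fwd))
  v_fwd <- pm_values(m_fwd)
  v_rev <- pm_values(m_rev)
  expect_equal(v_rev[rownames(v_fwd), ], v_fwd)
})

test_that("replicate averaging means duplicates, honours exclusions, and is idempotent", {
  pls <- list(make_peak_list(c(3000, 4000), c(4, 8), "s1", 1),
              make_peak_list(3000, 0.5, "s1", 2),
              make_peak_list(c(3000, 4000), c(2, 6), "s2", 1),
              make_peak_list(c(3000, 4000), c(4, 2), "s2", 2))
  # give s1 replicate 2 no 4000 peak: averaged value (8 + 0)/2 = 4
  m <- bin_peaks(pls, tolerance = 1e-4)
  man <- validate_manifest(tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s2"), group = c("A", "A", "B", "B"),
    replicate = c(1L, 2L, 1L, 2L)))
  avg <- average_replicates(m, man)
  expect_equal(nrow(avg), 2)
  v <- pm_values(avg)
  expect_equal(unname(v["s1", ]), c((4 + 0.5) / 2, (8 + 0) / 2))
  expect_equal(unname(v["s2", ]), c(3, 4))
  # idempotent on an averaged matrix
  expect_identical(average_replicates(avg, man), avg)
  # exclusion: drop s2 replicate 2 -> s2 row equals its replicate 1
  man2 <- man; man2$excluded[4] <- TRUE
  v2 <- pm_values(average_replicates(m, man2))
  expect_equal(unname(v2["s2", ]), c(2, 6))
  # unknown row -> error
  expect_error(average_replicates(m, man[-1, ]), "without manifest entry")
})

test_that("occurrence filter applies the boundary at >= min_frac and is monotone", {
  # 76 rows; bin A present in 25 rows (32.9% -> dropped), bin B in 26 (34.2% -> kept)
  v <- matrix(0, 76, 2)
  v[1:25, 1] <- 5
  v[1:26, 2] <- 5
  m <- make_matrix(v, refs = c(3000, 4000), binary = FALSE)
  kept <- filter_occurrence(m, 0.33)
  expect_equal(bin_masses(kept), 4000)

  sp <- small_pipeline()
  m_all <- filter_occurrence(sp$stage$matrix_replicates, 1e-9)
  expect_equal(bin_masses(m_all), bin_masses(sp$stage$matrix_replicates))
  expect_error(filter_occurrence(m, 0.9), "lower the occurrence")

  # monotone: raising min_frac never adds bins
  fracs <- c(0.1, 0.33, 0.6, 0.9)
  sets <- lapply(fracs, function(f)
    tryCatch(bin_masses(filter_occurrence(sp$stage$matrix_replicates, f)),
             error = function(e) numeric(0)))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})
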
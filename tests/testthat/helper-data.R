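# Shared fixtures: a reduced three-group simulation (same generator defaults,
# smaller n and mass window) and its pipeline products, computed once.

small_sim_config <- function(n = c(CTL = 6L, IS = 6L, LPS = 6L),
                             mz_range = c(2000, 8000), ...) {
  full <- default_paper_like_config()
  tpl <- lapply(full$templates, function(t) {
    k <- t$peak_mzs >= mz_range[1] + 150 & t$peak_mzs <= mz_range[2] - 150
    group_template(t$label, t$peak_mzs[k], t$presence_probs[k],
                   t$log_mean_intensity[k], t$log_sd[k])
  })
  sim_config(tpl, n_samples = n, mz_range = mz_range, ...)
}

sample_labels <- function(manifest, ids) {
  manifest$group[match(ids, manifest$sample_id)]
}

small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim_config()
      ds <- generate_dataset(sim, seed = 101)
      st <- build_peak_matrix(ds$spectra, ds$manifest)
      pm <- st$matrix
      labels <- sample_labels(ds$manifest, pm$sample_id)
      b <- dichotomize(pm, labels)
      cache <<- list(sim = sim, ds = ds, stage = st, pm = pm,
                     labels = labels, binary = b)
    }
    cache
  }
})

# binary/peak matrix from a plain 0/1 (or numeric) matrix, via the public
# CSV round-trip
make_matrix <- function(v, refs = NULL, sample_id = NULL, binary = TRUE) {
  refs <- refs %||% seq(3000, by = 500, length.out = ncol(v))
  sample_id <- sample_id %||% sprintf("s%02d", seq_len(nrow(v)))
  df <- tibble::as_tibble(as.data.frame(v))
  names(df) <- sprintf("mz_%.4f", refs)
  df <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id), df)
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  read_peak_matrix(path, binary = binary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-size study-condition run (76 samples in duplicate), computed once and
# shared by the end-to-end checks
full_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- default_paper_like_config()
      ds <- generate_dataset(sim, seed = 1)
      st <- build_peak_matrix(ds$spectra, ds$manifest)
      pm <- st$matrix
      labels <- sample_labels(ds$manifest, pm$sample_id)
      b <- dichotomize(pm, labels)
      rk <- bda_tscores(b, labels)
      top10 <- select_top_k(rk, 10)
      cl <- hkmeans(select_bins(b, top10), k = 3, labels = labels)
      split <- split_train_test(ds$manifest, 0.6, seed = 2)
      perf <- evaluate_grid(pm, ds$manifest, split, cv_folds = 5L,
                            cv_repeats = 20L, seed = 3)
      cache <<- list(sim = sim, ds = ds, pm = pm, labels = labels,
                     binary = b, ranking = rk, top10 = top10,
                     cluster = cl, split = split, perf = perf)
    }
    cache
  }
})

# hand-built peak list (as detect_peaks would emit) for binning tests
make_peak_list <- function(mz, intensity = NULL, sample_id = "s1",
                           replicate = 1L) {
  intensity <- intensity %||% rep(10, length(mz))
  structure(tibble::tibble(mz = mz, intensity = intensity,
                           snr = rep(10, length(mz))),
            class = c("peak_list", class(tibble::tibble())),
            sample_id = sample_id, replicate = as.integer(replicate),
            noise = 1)
}
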
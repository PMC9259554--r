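#' Build a replicate-averaged, occurrence-filtered peak matrix
#'
#' Runs the spectrum-level half of the pipeline: preprocessing
#' (trim, sqrt, Savitzky-Golay, SNIP), MAD/SNR peak detection, divisive
#' binning across spectra, replicate averaging (honouring manifest
#' exclusions) and the minimum-occurrence filter.
#'
#' @param spectra List of [raw_spectrum()]s.
#' @param manifest A `sample_manifest` covering them.
#' @param config A [pipeline_config()].
#' @return A list with `processed` (list of processed spectra),
#'   `peak_lists`, `matrix_replicates` (per-spectrum rows),
#'   `matrix` (averaged + filtered `peak_matrix`).
#' @export
build_peak_matrix <- function(spectra, manifest, config = pipeline_config()) {
  processed <- lapply(spectra, preprocess_spectrum, config = config)
  peak_lists <- lapply(processed, detect_peaks, snr = config$snr,
                       half_window = config$peak_half_window)
  pm_rep <- bin_peaks(peak_lists, tolerance = config$bin_tolerance)
  pm_avg <- average_replicates(pm_rep, manifest)
  pm <- filter_occurrence(pm_avg, config$min_occurrence_frac)
  list(processed = processed, peak_lists = peak_lists,
       matrix_replicates = pm_rep, matrix = pm)
}

#' Run the full stratification pipeline and write its artifacts
#'
#' One-call driver used by the command-line script: simulate (or accept)
#' spectra, build the peak matrix, dichotomize, rank features, cluster
#' with homogeneity/coverage metrics, evaluate the supervised grid, and
#' write every table plus a reproducibility log into `outdir`.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param sim A [sim_config()] used when `spectra` is `NULL`.
#' @param spectra,manifest Optional pre-loaded data; when `NULL`, a
#'   synthetic dataset is generated from `sim`.
#' @param seed Master seed for simulation, split and evaluation.
#' @param k_values Peak panel sizes for the evaluation grid.
#' @return (Invisibly) a list with the peak matrix, rankings, cluster
#'   result, and `performance_eval`.
#' @export
run_pipeline <- function(outdir, config = pipeline_config(),
                         sim = default_paper_like_config(),
                         spectra = NULL, manifest = NULL, seed = 1L,
                         k_values = c(5L, 10L, 15L, 20L)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spectra)) {
    ds <- generate_dataset(sim, seed = seed)
    spectra <- ds$spectra
    manifest <- ds$manifest
  } else if (is.null(manifest)) {
    abort("Provide `manifest` along with `spectra`.")
  }
  write_manifest(manifest, file.path(outdir, "manifest.csv"))
  stage <- build_peak_matrix(spectra, manifest, config)
  pm <- stage$matrix
  write_peak_matrix(pm, file.path(outdir, "peak_matrix.csv"))
  labels <- manifest_labels(manifest, pm$sample_id)
  b <- dichotomize(pm, labels)
  write_peak_matrix(b, file.path(outdir, "binary_matrix.csv"))
  rk_bda <- bda_tscores(b, labels)
  write_ranking(rk_bda, file.path(outdir, "ranking_bda.csv"))
  rk_rf <- rf_importance_ranking(b, labels, n_trees = config$rf_trees,
                                 seed = derive_seed(seed, 3L))
  write_ranking(rk_rf, file.path(outdir, "ranking_rf.csv"))
  top10 <- select_top_k(rk_bda, min(10L, nrow(rk_bda)))
  cl <- hkmeans(select_bins(b, top10), k = config$n_clusters, labels = labels)
  readr::write_csv(cl$homogeneity, file.path(outdir, "cluster_homogeneity.csv"))
  readr::write_csv(cl$coverage, file.path(outdir, "cluster_coverage.csv"))
  split <- split_train_test(manifest, train_frac = config$train_frac,
                            seed = derive_seed(seed, 4L))
  perf <- evaluate_grid(pm, manifest, split,
                        k_values = k_values,
                        cv_folds = config$cv_folds,
                        cv_repeats = config$cv_repeats,
                        seed = derive_seed(seed, 5L),
                        n_trees = config$rf_trees)
  write_performance(perf, file.path(outdir, "performance.csv"))
  write_run_log(config, seed, file.path(outdir, "run_log.yaml"))
  invisible(list(matrix = pm, binary = b, ranking_bda = rk_bda,
                 ranking_rf = rk_rf, cluster = cl, performance = perf,
                 split = split, manifest = manifest))
}
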
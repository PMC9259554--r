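#' Write and read intermediate tables
#'
#' All tabular artifacts (peak matrices, binary matrices, feature rankings,
#' performance tables) serialise to headed CSV and round-trip up to float
#' formatting. Peak-matrix bin references are encoded in the column names
#' (`mz_<reference>`), so a re-read matrix reconstructs its bin structure.
#'
#' @param m,ranking,perf,df Object to write.
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_peak_matrix <- function(m, path) {
  readr::write_csv(as_tibble(as.data.frame(m)), path)
  invisible(path)
}

#' @rdname table_io
#' @param binary Read the file back as a `binary_matrix`.
#' @export
read_peak_matrix <- function(path, binary = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(sample_id = "c"))
  bin_cols <- grep("^mz_", names(df), value = TRUE)
  if (length(bin_cols) == 0L) abort("No `mz_` bin columns found in file.")
  refs <- as.numeric(sub("^mz_", "", bin_cols))
  v <- as.matrix(df[, bin_cols])
  new_peak_matrix(v, refs, sample_id = as.character(df$sample_id),
                  replicate = if ("replicate" %in% names(df)) df$replicate,
                  averaged = !"replicate" %in% names(df),
                  binary = binary)
}

#' @rdname table_io
#' @export
write_ranking <- function(ranking, path) {
  readr::write_csv(as_tibble(as.data.frame(ranking)), path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_ranking <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname table_io
#' @export
write_performance <- function(perf, path) {
  tab <- if (inherits(perf, "performance_eval")) {
    dplyr::bind_rows(dplyr::mutate(perf$test, evaluation = "test"),
                     dplyr::mutate(perf$cv, evaluation = "cv"))
  } else as_tibble(perf)
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_performance <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write the reproducibility log of a run
#'
#' Records the resolved configuration, the seed and a timestamp.
#'
#' @param config A `pipeline_config`.
#' @param seed The run's master seed.
#' @param path Output YAML path.
#' @export
write_run_log <- function(config, seed, path) {
  yaml::write_yaml(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                        seed = as.integer(seed),
                        config = unclass(config)), path)
  invisible(path)
}
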
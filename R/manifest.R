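#' Read and validate a sample manifest
#'
#' The manifest is a delimited table with one row per acquired spectrum and
#' columns `sample_id`, `group`, `replicate`, and optionally `file_path`
#' (where the spectrum lives on disk) and `excluded` (logical; replicates
#' dropped for quality before averaging).
#'
#' @param path Path to a CSV/TSV manifest with a header row.
#' @param check_files If `TRUE`, error when any `file_path` is missing on
#'   disk.
#' @return A tibble of class `sample_manifest`.
#' @export
read_manifest <- function(path, check_files = FALSE) {
  if (!file.exists(path)) abort(sprintf("Manifest not found: %s", path))
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  validate_manifest(df, check_files = check_files)
}

#' Validate a manifest data frame
#'
#' @param df Data frame with at least `sample_id`, `group`, `replicate`.
#' @inheritParams read_manifest
#' @return The validated manifest as a `sample_manifest` tibble.
#' @export
validate_manifest <- function(df, check_files = FALSE) {
  need <- c("sample_id", "group", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Manifest is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (nrow(df) == 0L) abort("Manifest has no data rows.")
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1L)) abort("Replicate indices must be >= 1.")
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  df$excluded[is.na(df$excluded)] <- FALSE
  key <- paste(df$sample_id, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("sample_id", "replicate")]
    abort(sprintf("Duplicated (sample_id, replicate) pairs in manifest: %s",
                  paste(unique(paste0(dup$sample_id, "/", dup$replicate)),
                        collapse = ", ")))
  }
  if (check_files) {
    if (!"file_path" %in% names(df)) {
      abort("`check_files = TRUE` but manifest has no `file_path` column.")
    }
    miss <- df$file_path[!file.exists(df$file_path)]
    if (length(miss)) {
      abort(sprintf("Manifest references missing spectrum files: %s",
                    paste(miss, collapse = ", ")))
    }
  }
  class(df) <- c("sample_manifest", class(tibble()))
  df
}

#' @export
print.sample_manifest <- function(x, ...) {
  counts <- manifest_counts(x)
  cat(sprintf("<sample_manifest> %d spectra, %d samples, %d excluded\n",
              nrow(x), length(unique(x$sample_id)), sum(x$excluded)))
  print(counts, ...)
  invisible(x)
}

#' Per-group sample and spectrum counts
#'
#' @param manifest A `sample_manifest`.
#' @return A tibble with one row per group: number of distinct samples,
#'   acquired spectra, and spectra retained after exclusions.
#' @export
manifest_counts <- function(manifest) {
  manifest |>
    dplyr::group_by(group) |>
    dplyr::summarise(n_samples = dplyr::n_distinct(.data$sample_id),
                     n_spectra = dplyr::n(),
                     n_retained = sum(!.data$excluded),
                     .groups = "drop")
}

#' @rdname read_manifest
#' @param manifest A `sample_manifest` to write.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(as_tibble(manifest), path)
  invisible(path)
}

# labels for a set of sample ids, in that order
manifest_labels <- function(manifest, sample_ids) {
  idx <- match(sample_ids, manifest$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("Sample id(s) not in manifest: %s",
                  paste(sample_ids[is.na(idx)], collapse = ", ")))
  }
  manifest$group[idx]
}
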
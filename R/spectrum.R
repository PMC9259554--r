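#' Construct a raw spectrum
#'
#' A raw spectrum is a tibble with columns `mz` (Da, strictly increasing) and
#' `intensity` (non-negative arbitrary counts), carrying the acquisition
#' metadata (`sample_id`, `group`, `replicate`) as attributes. Linear-mode
#' whole-plasma acquisitions nominally cover 2,000-20,000 Da.
#'
#' @param mz Numeric vector of masses in Da.
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param sample_id Sample identifier.
#' @param group Group label (e.g. `"CTL"`, `"IS"`, `"LPS"`; any label set).
#' @param replicate Positive integer replicate (spot) index.
#'
#' @return A tibble of class `raw_spectrum`. Input rows are sorted by `mz`.
#' @export
#'
#' @examples
#' raw_spectrum(c(2000, 2001), c(5, 6), sample_id = "s1")
raw_spectrum <- function(mz, intensity, sample_id = "sample",
                         group = NA_character_, replicate = 1L) {
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have the same length.")
  }
  if (length(mz) < 2L) abort("A spectrum needs at least 2 data points.")
  if (anyNA(mz) || anyNA(intensity)) abort("Spectrum contains missing values.")
  ord <- order(mz)
  mz <- as.numeric(mz[ord])
  intensity <- as.numeric(intensity[ord])
  if (anyDuplicated(mz)) {
    abort("Duplicate m/z values in spectrum; each mass must be unique.")
  }
  if (any(intensity < 0)) abort("Intensities must be non-negative.")
  out <- tibble(mz = mz, intensity = intensity)
  new_spectrum_tbl(out, "raw_spectrum",
                   sample_id = as.character(sample_id),
                   group = as.character(group),
                   replicate = as.integer(replicate))
}

new_spectrum_tbl <- function(df, class1, sample_id, group, replicate,
                             provenance = list()) {
  structure(df,
            class = c(class1, class(tibble())),
            sample_id = sample_id, group = group, replicate = replicate,
            provenance = provenance)
}

spectrum_meta <- function(s) {
  list(sample_id = attr(s, "sample_id") %||% NA_character_,
       group = attr(s, "group") %||% NA_character_,
       replicate = attr(s, "replicate") %||% NA_integer_)
}

#' @export
print.raw_spectrum <- function(x, ...) {
  m <- spectrum_meta(x)
  cat(sprintf("<raw_spectrum> %s (group %s, replicate %s): %d points, %.1f-%.1f Da\n",
              m$sample_id, m$group, m$replicate, nrow(x), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Reads a single profile spectrum from two-column delimited text (m/z,
#' intensity; the native exchange format here) or from an mzML file via the
#' `mzR` package. Rows out of mass order are sorted; duplicated masses are an
#' error rather than silently merged.
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"csv"`, `"mzml"`. Defaults from the file
#'   extension.
#' @param scan For mzML input, which scan to read (default 1).
#' @inheritParams raw_spectrum
#'
#' @return A [raw_spectrum()].
#' @export
read_spectrum <- function(path, format = NULL, sample_id = NULL,
                          group = NA_character_, replicate = 1L, scan = 1L) {
  if (!file.exists(path)) abort(sprintf("Spectrum file not found: %s", path))
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               csv = "csv", mzml = "mzml", "tsv")
  format <- match.arg(format, c("tsv", "csv", "mzml"))
  sample_id <- sample_id %||% tools::file_path_sans_ext(basename(path))
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort("Reading mzML requires the 'mzR' package.")
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h), add = TRUE)
    pk <- mzR::peaks(h, scan)
    return(raw_spectrum(pk[, 1], pk[, 2], sample_id = sample_id,
                        group = group, replicate = replicate))
  }
  delim <- if (format == "csv") "," else NULL
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) abort(sprintf("Empty spectrum file: %s", path))
  # tolerate an optional header line
  first_data <- 1L
  if (is.na(suppressWarnings(as.numeric(first_token(raw[1], delim))))) {
    first_data <- 2L
  }
  rows <- lapply(seq(first_data, length(raw)), function(i) {
    tok <- if (is.null(delim)) strsplit(trimws(raw[i]), "[[:space:]]+")[[1]]
           else strsplit(trimws(raw[i]), delim, fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      abort(sprintf("Non-numeric spectrum row at line %d of %s: '%s'",
                    i, path, raw[i]))
    }
    vals[1:2]
  })
  if (length(rows) < 2L) abort(sprintf("Spectrum %s has fewer than 2 points.", path))
  m <- do.call(rbind, rows)
  raw_spectrum(m[, 1], m[, 2], sample_id = sample_id, group = group,
               replicate = replicate)
}

first_token <- function(line, delim) {
  tok <- if (is.null(delim)) strsplit(trimws(line), "[[:space:]]+")[[1]]
         else strsplit(trimws(line), delim, fixed = TRUE)[[1]]
  tok[1]
}

#' Write a spectrum as two-column delimited text
#'
#' @param s A spectrum (raw or processed); only `mz` and `intensity` are
#'   written.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  df <- tibble(mz = s$mz, intensity = s$intensity)
  if (format == "csv") readr::write_csv(df, path) else readr::write_tsv(df, path)
  invisible(path)
}
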
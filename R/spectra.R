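#' Construct a validated set of reflectance scans
#'
#' The central container for raw scans: a scan-by-band reflectance matrix
#' with its wavenumber axis and per-scan metadata (sample id, replicate
#' index, management mode).
#'
#' @param wavenumbers Strictly increasing numeric vector of cm-1 values.
#' @param reflectance Numeric matrix, one row per scan, one column per
#'   band; values must be finite and in (0, 1].
#' @param sample_id Character vector, one entry per scan.
#' @param replicate Integer replicate index per scan.
#' @param mode Management-mode label per scan.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, reflectance, sample_id,
                         replicate = rep(1L, length(sample_id)),
                         mode = rep(NA_character_, length(sample_id))) {
  reflectance <- as.matrix(reflectance)
  if (ncol(reflectance) != length(wavenumbers)) {
    stopf("reflectance has %d columns but %d wavenumbers given",
          ncol(reflectance), length(wavenumbers))
  }
  if (nrow(reflectance) != length(sample_id)) {
    stopf("reflectance has %d rows but %d sample ids given",
          nrow(reflectance), length(sample_id))
  }
  if (any(diff(wavenumbers) <= 0)) {
    stopf("wavenumbers must be strictly increasing")
  }
  if (anyNA(reflectance) || any(!is.finite(reflectance))) {
    bad <- which(!is.finite(reflectance), arr.ind = TRUE)[1, ]
    stopf("missing/non-finite reflectance at row %d, band column %d",
          bad[1], bad[2])
  }
  if (any(reflectance <= 0)) {
    bad <- which(reflectance <= 0, arr.ind = TRUE)[1, ]
    stopf("non-positive reflectance at row %d, band column %d",
          bad[1], bad[2])
  }
  # replicate counts must be balanced within a raw scan set
  counts <- table(sample_id)
  structure(list(
    wavenumbers = as.numeric(wavenumbers),
    reflectance = unname(reflectance),
    sample_id = as.character(sample_id),
    replicate = as.integer(replicate),
    mode = as.character(mode)
  ), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "spectrum_set: %d scans x %d bands, %d samples, %.1f-%.1f cm-1\n",
    nrow(x$reflectance), length(x$wavenumbers),
    length(unique(x$sample_id)), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @export
print.sample_spectra <- function(x, ...) {
  cat(sprintf(
    "sample_spectra: %d samples x %d bands (%s replicate scans averaged)\n",
    nrow(x$reflectance), length(x$wavenumbers),
    attr(x, "n_averaged") %||% "?"))
  invisible(x)
}

#' Write a spectrum set as a wide CSV
#'
#' Layout: `sample_id,replicate,mode,<wavenumber_1>,...,<wavenumber_n>`,
#' comma-separated, '.' decimal, UTF-8.  Wavenumber headers are printed
#' with at most 4 decimal places; reflectance values are printed with
#' full double precision so a write-read round trip is exact.
#'
#' @param set A `spectrum_set` or `sample_spectra` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set") || inherits(set, "sample_spectra"))
  # wavenumber axis is stored at <= 4 decimal places; print as-is
  wn_str <- sub("0+$", "", sprintf("%.4f", set$wavenumbers))
  wn_str <- sub("\\.$", "", wn_str)
  header <- c("sample_id", "replicate", "mode", wn_str)
  vals <- apply(set$reflectance, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  })
  repl <- set$replicate %||% rep(1L, nrow(set$reflectance))
  lines <- paste(set$sample_id, repl, set$mode, vals, sep = ",")
  writeLines(c(paste(header, collapse = ","), lines), path, useBytes = TRUE)
  invisible(path)
}

#' Write a tannin reference table as a two-column CSV
#'
#' @param tannins Data frame with `sample_id` and `tannin` (mg/g).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tannin_csv <- function(tannins, path) {
  lines <- paste(tannins$sample_id, sprintf("%.17g", tannins$tannin),
                 sep = ",")
  writeLines(c("sample_id,tannin", lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a tannin reference table
#'
#' @param path CSV file with columns `sample_id`, `tannin`.
#' @return Data frame with `sample_id` (character) and `tannin` (numeric).
#' @export
read_tannin_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tannin") %in% names(df))) {
    stopf("format error: expected columns sample_id, tannin in %s", path)
  }
  if (anyNA(df$tannin) || any(df$tannin <= 0)) {
    stopf("format error: tannin values must be positive and non-missing")
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a wide spectra CSV
#'
#' Expects the layout written by [write_spectra_csv()].  Wavenumber columns
#' must be numeric and strictly monotonic; files stored in descending
#' wavenumber order are accepted and flipped to ascending with a notice.
#'
#' @param path CSV file path.
#' @param verbose Emit a message with the parsed dimensions (default TRUE).
#' @return A validated `spectrum_set`.
#' @export
read_spectra_csv <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "replicate", "mode")
  if (!all(meta_cols %in% names(df)[1:3])) {
    stopf("format error: first columns must be %s",
          paste(meta_cols, collapse = ","))
  }
  wn <- suppressWarnings(as.numeric(names(df)[-(1:3)]))
  if (anyNA(wn)) {
    bad <- names(df)[-(1:3)][which(is.na(wn))[1]]
    stopf("format error: non-numeric wavenumber column header '%s'", bad)
  }
  mat <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stopf("format error: missing value at data row %d, band column %d",
          bad[1], bad[2])
  }
  d <- diff(wn)
  if (all(d < 0)) {
    msgf(verbose, "wavenumbers descending in %s; flipping to ascending",
         basename(path))
    wn <- rev(wn)
    mat <- mat[, rev(seq_along(wn)), drop = FALSE]
  } else if (any(d <= 0)) {
    stopf("format error: wavenumber axis not strictly monotonic near column %d",
          which(d <= 0)[1] + 3)
  }
  set <- spectrum_set(wn, mat, df$sample_id, df$replicate, df$mode)
  msgf(verbose, "read %d scans x %d bands from %s",
       nrow(mat), length(wn), basename(path))
  set
}

#' Average replicate scans to one spectrum per sample
#'
#' Band-wise arithmetic mean over each sample's replicate scans, the
#' standard reduction from repeated instrument scans to a representative
#' spectrum per sample.
#'
#' @param set A `spectrum_set` of raw scans.
#' @return A `sample_spectra` object: one row per distinct sample id, in
#'   first-appearance order, with attribute `n_averaged` recording the
#'   replicate counts collapsed.
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  ids <- unique(set$sample_id)
  out <- matrix(0, length(ids), length(set$wavenumbers))
  mode_out <- character(length(ids))
  for (i in seq_along(ids)) {
    rows <- which(set$sample_id == ids[i])
    out[i, ] <- colMeans(set$reflectance[rows, , drop = FALSE])
    mode_out[i] <- set$mode[rows[1]]
  }
  res <- structure(list(
    wavenumbers = set$wavenumbers,
    reflectance = out,
    sample_id = ids,
    mode = mode_out
  ), class = c("sample_spectra", "spectrum_set"))
  attr(res, "n_averaged") <-
    paste(sort(unique(table(set$sample_id))), collapse = "/")
  res
}
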
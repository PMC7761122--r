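#' Spectral dataset container
#'
#' The central object of the pipeline: a strictly increasing wavelength grid,
#' a samples-by-wavelength numeric matrix, the photometric mode, and optional
#' per-sample metadata (storage day, reference juiciness in percent).
#'
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm).
#' @param spectra numeric matrix, one row per sample, one column per
#'   wavelength. A vector is treated as a single spectrum.
#' @param mode `"absorbance"` or `"transmittance_pct"`. Transmittance values
#'   must be non-negative.
#' @param sample_ids optional character vector of sample identifiers.
#' @param day optional integer vector of sampling occasions (storage days),
#'   used by [split_calibration_validation()].
#' @param reference optional numeric vector of reference values
#'   (juiciness, percent).
#'
#' @return An object of class `spectral_dataset`.
#' @seealso [read_spectra_csv()], [write_spectra_csv()], [generate_dataset()]
#' @export
spectral_dataset <- function(wavelengths, spectra,
                             mode = c("absorbance", "transmittance_pct"),
                             sample_ids = NULL, day = NULL, reference = NULL) {
  mode <- match.arg(mode)
  spectra <- as_spectra_matrix(spectra)
  wavelengths <- check_wavelengths(wavelengths, ncol(spectra))
  n <- nrow(spectra)
  if (mode == "transmittance_pct" && any(spectra < 0))
    stop("transmittance values must be >= 0")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length must match sample count")
  if (!is.null(day)) {
    day <- as.integer(day)
    if (length(day) != n || anyNA(day)) stop("day must be one integer per sample")
  }
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != n || anyNA(reference))
      stop("reference must be one numeric value per sample")
  }
  colnames(spectra) <- format(wavelengths, trim = TRUE)
  rownames(spectra) <- sample_ids
  structure(
    list(wavelengths = wavelengths, spectra = spectra, mode = mode,
         sample_ids = sample_ids, day = day, reference = reference),
    class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d wavelengths (%.0f-%.0f nm), mode = %s\n",
              nrow(x$spectra), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$mode))
  if (!is.null(x$day))
    cat(sprintf("  days: %s\n", paste(sort(unique(x$day)), collapse = " ")))
  if (!is.null(x$reference))
    cat(sprintf("  reference: %.2f-%.2f %% (mean %.2f)\n",
                min(x$reference), max(x$reference), mean(x$reference)))
  invisible(x)
}

#' Subset a spectral dataset by sample
#'
#' @param dataset a [spectral_dataset()].
#' @param idx integer or logical index over samples.
#' @return A `spectral_dataset` with the selected samples.
#' @export
dataset_subset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  spectral_dataset(dataset$wavelengths,
                   dataset$spectra[idx, , drop = FALSE],
                   mode = dataset$mode,
                   sample_ids = dataset$sample_ids[idx],
                   day = if (!is.null(dataset$day)) dataset$day[idx],
                   reference = if (!is.null(dataset$reference)) dataset$reference[idx])
}

#' Write / read the spectra CSV dialect
#'
#' The on-disk layout is a plain UTF-8 comma-separated table: first column
#' `sample_id`, optional `day` column, one column per wavelength (header is
#' the wavelength in nm as a plain number), and an optional final `juiciness`
#' column holding the reference values. Round-trips through
#' [read_spectra_csv()] reproduce the dataset.
#'
#' @param dataset a [spectral_dataset()].
#' @param path file path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns a `spectral_dataset`.
#' @export
write_spectra_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  df <- data.frame(sample_id = dataset$sample_ids, stringsAsFactors = FALSE)
  if (!is.null(dataset$day)) df$day <- dataset$day
  sp <- as.data.frame(dataset$spectra)
  names(sp) <- format(dataset$wavelengths, trim = TRUE)
  df <- cbind(df, sp)
  if (!is.null(dataset$reference)) df$juiciness <- dataset$reference
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param mode photometric mode to stamp on the dataset read from disk.
#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, mode = c("absorbance", "transmittance_pct")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing 'sample_id' column")
  ids <- as.character(df$sample_id)
  day <- if ("day" %in% names(df)) df$day
  reference <- if ("juiciness" %in% names(df)) df$juiciness
  wl_cols <- setdiff(names(df), c("sample_id", "day", "juiciness"))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl))
    stop(sprintf("non-numeric wavelength header(s): %s",
                 paste(wl_cols[is.na(wl)], collapse = ", ")))
  if (any(diff(wl) <= 0)) stop("wavelength columns are not strictly increasing")
  spectra <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, wl_cols, drop = FALSE])), nrow(df)))
  if (anyNA(spectra)) {
    bad <- which(is.na(spectra), arr.ind = TRUE)
    stop(sprintf("non-numeric or missing spectral cells (first at row %d, column %s)",
                 bad[1, 1], wl_cols[bad[1, 2]]))
  }
  spectral_dataset(wl, spectra, mode = mode, sample_ids = ids,
                   day = day, reference = reference)
}
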
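#' Transmittance from raw instrument intensities
#'
#' Converts a sample intensity spectrum into percent transmittance using the
#' dark-current and white-reference spectra recorded alongside it:
#' `T = (I - D) / (R - D) * 100`.
#'
#' @param intensity sample intensity spectrum `I`.
#' @param dark dark-current spectrum `D` (no illumination).
#' @param white white-reference spectrum `R`.
#' @param wavelengths optional wavelengths, only used to name the offending
#'   position in error messages.
#' @return Numeric vector of percent transmittance.
#' @export
compute_transmittance <- function(intensity, dark, white, wavelengths = NULL) {
  n <- length(intensity)
  if (length(dark) != n || length(white) != n)
    stop("intensity, dark and white spectra must have equal length")
  denom <- white - dark
  if (any(denom == 0)) {
    at <- which(denom == 0)[1]
    lab <- if (is.null(wavelengths)) sprintf("index %d", at)
           else sprintf("%g nm", wavelengths[at])
    stop(sprintf("white and dark spectra coincide at %s; transmittance undefined", lab))
  }
  (intensity - dark) / denom * 100
}

#' Convert between percent transmittance and absorbance
#'
#' Calibration is run on absorbance by default (`A = -log10(T/100)`), the
#' domain in which the chemical signal is linear in constituent
#' concentration (Beer-Lambert). The inverse, `T = 100 * 10^(-A)`, is exact.
#'
#' @param dataset a [spectral_dataset()] in `transmittance_pct` mode
#'   (or `absorbance` mode for the inverse).
#' @return A `spectral_dataset` in the other mode.
#' @export
transmittance_to_absorbance <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (dataset$mode != "transmittance_pct")
    stop("dataset is not in transmittance mode")
  if (any(dataset$spectra <= 0)) {
    bad <- which(dataset$spectra <= 0, arr.ind = TRUE)
    stop(sprintf(
      "non-positive transmittance in %d cell(s); first at sample %s, %s nm",
      nrow(bad), dataset$sample_ids[bad[1, 1]],
      format(dataset$wavelengths[bad[1, 2]])))
  }
  out <- dataset
  out$spectra[] <- -log10(dataset$spectra / 100)
  out$mode <- "absorbance"
  out
}

#' @rdname transmittance_to_absorbance
#' @export
absorbance_to_transmittance <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (dataset$mode != "absorbance") stop("dataset is not in absorbance mode")
  out <- dataset
  out$spectra[] <- 100 * 10^(-dataset$spectra)
  out$mode <- "transmittance_pct"
  out
}

#' Juiciness reference value from a compression weight pair
#'
#' The reference juiciness is computed from the pulp weight before (`w1`) and
#' after (`w2`) the texture-analyzer compression as
#' `J = (w2 - w1) / w1 * 100`. As printed this is negative whenever the pulp
#' loses mass under compression, while reference juiciness values are
#' reported positive; `sign_convention = "mass_loss"` flips the sign to
#' `(w1 - w2) / w1 * 100` for rigs where `w2` is the post-compression pulp
#' weight rather than the expressed-juice mass. The default reproduces the
#' printed formula and never silently corrects it.
#'
#' @param w1 pulp weight before compression (must be > 0).
#' @param w2 weight after compression (same units).
#' @param sign_convention `"as_printed"` (default) or `"mass_loss"`.
#' @return Juiciness in percent (vectorized).
#' @export
compute_juiciness <- function(w1, w2, sign_convention = c("as_printed", "mass_loss")) {
  sign_convention <- match.arg(sign_convention)
  if (any(w1 <= 0)) stop("w1 must be strictly positive")
  j <- (w2 - w1) / w1 * 100
  if (sign_convention == "mass_loss") -j else j
}

#' Average replicate spectra
#'
#' Each sample is scanned several times (three in the reference protocol);
#' replicates sharing a group id are reduced to their arithmetic mean.
#'
#' @param spectra numeric matrix, one row per scan.
#' @param group_ids vector assigning each row to a sample.
#' @return Matrix with one row per group, in first-appearance order of
#'   `group_ids`.
#' @export
average_replicates <- function(spectra, group_ids) {
  spectra <- as_spectra_matrix(spectra)
  if (length(group_ids) != nrow(spectra))
    stop("group_ids length must match row count")
  groups <- unique(group_ids)
  out <- matrix(NA_real_, length(groups), ncol(spectra),
                dimnames = list(as.character(groups), colnames(spectra)))
  for (i in seq_along(groups)) {
    rows <- which(group_ids == groups[i])
    if (length(rows) == 0L) stop(sprintf("empty replicate group '%s'", groups[i]))
    out[i, ] <- colMeans(spectra[rows, , drop = FALSE])
  }
  out
}

#' Day-stratified calibration / validation split
#'
#' Draws a fixed number of calibration samples at random from every sampling
#' occasion (storage day); the remainder form the external validation set.
#' With ten occasions and `per_day = 10` this reproduces the 100 / 27 split
#' of a 127-sample storage experiment.
#'
#' @param dataset a [spectral_dataset()] with a `day` vector.
#' @param per_day number of calibration samples to draw per day.
#' @param seed integer seed; the split is reproducible given the seed.
#' @return A list of class `split_result` with disjoint integer vectors
#'   `calibration` and `validation` whose union covers all samples, plus the
#'   seed used.
#' @export
split_calibration_validation <- function(dataset, per_day = 10L, seed = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (is.null(dataset$day))
    stop("dataset has no 'day' metadata; a day-stratified split needs it")
  per_day <- as.integer(per_day)
  days <- sort(unique(dataset$day))
  counts <- table(dataset$day)
  short <- names(counts)[counts < per_day]
  if (length(short))
    stop(sprintf("day(s) %s have fewer than %d samples",
                 paste(short, collapse = ", "), per_day))
  cal <- with_seed(seed, {
    unlist(lapply(days, function(d) {
      idx <- which(dataset$day == d)
      sort(sample(idx, per_day))
    }))
  })
  cal <- sort(cal)
  structure(list(calibration = cal,
                 validation = setdiff(seq_along(dataset$sample_ids), cal),
                 per_day = per_day, seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d validation samples (%d per day)\n",
              length(x$calibration), length(x$validation), x$per_day))
  invisible(x)
}
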
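#' @title Scatter-correction preprocessing
#' @description
#' Nine preprocessing methods for removing additive and multiplicative
#' scatter effects from spectra, plus Savitzky-Golay smoothing and the
#' spectral-ratio variable construction. Five methods (NOR, SNV, MSC, PQN,
#' LRC) assume a constant additive offset per sample
#' (`x = a * x_chem + b`); DET, OPS and OPLECm assume a
#' wavelength-dependent additive baseline in span `{1, lambda, lambda^2}`.
#' LRC and OPS remove only the additive part, leaving the multiplicative
#' effect for the spectral-ratio step to cancel.
#' @name preprocessing
NULL

preprocess_result <- function(corrected, method, estimated_scatter = NULL,
                              reference_spectrum = NULL) {
  structure(list(corrected = corrected, method = method,
                 estimated_scatter = estimated_scatter,
                 reference_spectrum = reference_spectrum),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat(sprintf("<preprocess_result> method %s: %d samples x %d variables\n",
              x$method, nrow(x$corrected), ncol(x$corrected)))
  invisible(x)
}

#' Savitzky-Golay smoothing
#'
#' Per-row least-squares polynomial smoothing (default: second-order
#' polynomial, 9-point window) applied before any scatter correction. Edges
#' are handled by evaluating the polynomial fitted on the first/last full
#' window at the edge positions, so polynomials up to `polyorder` pass
#' through unchanged everywhere.
#'
#' @param spectra numeric matrix (samples x wavelengths) or vector.
#' @param window odd window width in points.
#' @param polyorder polynomial order, less than `window`.
#' @return Smoothed matrix of the same shape.
#' @export
sg_smooth <- function(spectra, window = 9L, polyorder = 2L) {
  spectra <- as_spectra_matrix(spectra)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > ncol(spectra)) stop("window exceeds spectrum length")
  out <- t(apply(spectra, 1, signal::sgolayfilt, p = polyorder, n = window))
  dimnames(out) <- dimnames(spectra)
  out
}

#' Normalization (NOR)
#'
#' Scales each spectrum to unit Euclidean norm (or unit total absolute
#' area with `type = "area"`), removing pure multiplicative scatter.
#'
#' @param spectra numeric matrix (samples x wavelengths).
#' @param type `"euclidean"` (default) or `"area"`.
#' @return A `preprocess_result`.
#' @export
normalize_nor <- function(spectra, type = c("euclidean", "area")) {
  type <- match.arg(type)
  spectra <- as_spectra_matrix(spectra)
  s <- if (type == "euclidean") sqrt(rowSums(spectra^2)) else rowSums(abs(spectra))
  if (any(s == 0)) stop("cannot normalize an all-zero spectrum")
  preprocess_result(spectra / s, "NOR")
}

#' First derivative (FD)
#'
#' Savitzky-Golay first derivative (same window and polynomial order as the
#' smoothing step), scaled by the grid step so units are absorbance per nm.
#' Removes any constant additive offset.
#'
#' @inheritParams sg_smooth
#' @param wavelengths uniform wavelength grid in nm.
#' @return A `preprocess_result`.
#' @export
first_derivative <- function(spectra, wavelengths, window = 9L, polyorder = 2L) {
  spectra <- as_spectra_matrix(spectra)
  wavelengths <- check_wavelengths(wavelengths, ncol(spectra))
  step <- diff(wavelengths)
  if (max(step) - min(step) > 1e-8 * mean(step))
    stop("first_derivative requires a uniform wavelength grid")
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > ncol(spectra)) stop("window exceeds spectrum length")
  out <- t(apply(spectra, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = 1, ts = step[1]))
  dimnames(out) <- dimnames(spectra)
  preprocess_result(out, "FD")
}

#' Detrend (DET)
#'
#' Subtracts a per-row least-squares polynomial in wavelength (default
#' degree 2, matching the `{1, lambda, lambda^2}` additive baseline model),
#' leaving residuals orthogonal to that span.
#'
#' @param spectra numeric matrix (samples x wavelengths).
#' @param wavelengths wavelength grid in nm.
#' @param degree polynomial degree (`0` reduces to row mean-centering).
#' @return A `preprocess_result`.
#' @export
detrend <- function(spectra, wavelengths, degree = 2L) {
  spectra <- as_spectra_matrix(spectra)
  wavelengths <- check_wavelengths(wavelengths, ncol(spectra))
  if (degree >= ncol(spectra)) stop("degree must be below the spectrum length")
  B <- baseline_basis(wavelengths, degree)
  preprocess_result(spectra - (spectra %*% B) %*% t(B), "DET")
}

#' Standard normal variate (SNV)
#'
#' Centers each spectrum by its own mean and scales by its own standard
#' deviation (n - 1 denominator). Invariant to the constant-offset scatter
#' transform `x -> a * x + b` (a > 0).
#'
#' @param spectra numeric matrix (samples x wavelengths).
#' @return A `preprocess_result`.
#' @export
snv <- function(spectra) {
  spectra <- as_spectra_matrix(spectra)
  m <- rowMeans(spectra)
  s <- apply(spectra, 1, stats::sd)
  if (any(s == 0)) stop("SNV undefined for a zero-variance spectrum")
  preprocess_result((spectra - m) / s, "SNV")
}

# per-row least-squares fit x ~ b + a * reference; returns a and b vectors
affine_fit <- function(spectra, reference) {
  rc <- reference - mean(reference)
  v <- sum(rc^2)
  if (v == 0) stop("reference spectrum must not be constant")
  a <- as.numeric(spectra %*% rc) / v
  b <- rowMeans(spectra) - a * mean(reference)
  list(a = a, b = b)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum
#' (`x_i ~ b_i + a_i * reference`, reference defaulting to the mean of the
#' input rows) and inverts the fit: `corrected_i = (x_i - b_i) / a_i`. The
#' reference must be estimated on the calibration set and passed in when
#' correcting validation spectra.
#'
#' @param spectra numeric matrix (samples x wavelengths).
#' @param reference reference spectrum; default `colMeans(spectra)`.
#' @param tol samples whose fitted slope has `|a_i| < tol` raise an error.
#' @return A `preprocess_result` carrying the estimated per-sample `(a, b)`
#'   as a [scatter_params()] and the reference spectrum used.
#' @export
msc <- function(spectra, reference = NULL, tol = 1e-10) {
  spectra <- as_spectra_matrix(spectra)
  if (is.null(reference)) reference <- colMeans(spectra)
  fit <- affine_fit(spectra, reference)
  if (any(abs(fit$a) < tol))
    stop(sprintf("MSC slope below tolerance for sample(s) %s",
                 paste(which(abs(fit$a) < tol), collapse = ", ")))
  preprocess_result((spectra - fit$b) / fit$a, "MSC",
                    estimated_scatter = estimated_scatter_params(fit$a, fit$b),
                    reference_spectrum = reference)
}

#' Probabilistic quotient normalization (PQN)
#'
#' Each spectrum is first integral-normalized (divided by its own sum) and
#' then divided by the median over wavelengths of its quotient against a
#' reference spectrum (default: the column-wise median of the
#' integral-normalized input rows, which must be strictly positive).
#'
#' @param spectra numeric matrix (samples x wavelengths).
#' @param reference reference spectrum on the integral-normalized scale.
#' @return A `preprocess_result` carrying the reference spectrum used.
#' @export
pqn <- function(spectra, reference = NULL) {
  spectra <- as_spectra_matrix(spectra)
  rs <- rowSums(spectra)
  if (any(rs == 0)) stop("PQN undefined for a zero-sum spectrum")
  normed <- spectra / rs
  if (is.null(reference)) reference <- apply(normed, 2, stats::median)
  if (any(reference <= 0))
    stop("PQN reference spectrum must be strictly positive")
  q <- apply(normed / rep(reference, each = nrow(normed)), 1, stats::median)
  preprocess_result(normed / q, "PQN", reference_spectrum = reference)
}

#' Linear regression correction (LRC)
#'
#' Like [msc()], fits `x_i ~ b_i + a_i * reference`, but removes only the
#' additive offset: `corrected_i = x_i - b_i`. The multiplicative effect is
#' deliberately retained so the subsequent spectral-ratio step
#' ([build_spectral_ratios()]) can cancel it.
#'
#' @inheritParams msc
#' @return A `preprocess_result` with the estimated `(a, b)` and reference.
#' @export
lrc_correct <- function(spectra, reference = NULL, tol = 1e-10) {
  spectra <- as_spectra_matrix(spectra)
  if (is.null(reference)) reference <- colMeans(spectra)
  fit <- affine_fit(spectra, reference)
  if (any(abs(fit$a) < tol))
    stop(sprintf("LRC slope below tolerance for sample(s) %s",
                 paste(which(abs(fit$a) < tol), collapse = ", ")))
  preprocess_result(spectra - fit$b, "LRC",
                    estimated_scatter = estimated_scatter_params(fit$a, fit$b),
                    reference_spectrum = reference)
}

#' Orthogonal spatial projection (OPS)
#'
#' Projects each spectrum onto the orthogonal complement of
#' span `{1, lambda, lambda^2}` (wavelengths rescaled to `[-1, 1]` for
#' conditioning), exactly annihilating any wavelength-dependent additive
#' baseline of that form. Idempotent; output rows have zero inner product
#' with each basis vector.
#'
#' @param spectra numeric matrix (samples x wavelengths).
#' @param wavelengths wavelength grid in nm (at least 4 points).
#' @param degree polynomial degree of the removed span (default 2).
#' @return A `preprocess_result`.
#' @export
ops_project <- function(spectra, wavelengths, degree = 2L) {
  spectra <- as_spectra_matrix(spectra)
  wavelengths <- check_wavelengths(wavelengths, ncol(spectra))
  if (ncol(spectra) < degree + 2L)
    stop("need more wavelengths than baseline basis vectors")
  B <- baseline_basis(wavelengths, degree)
  preprocess_result(spectra - (spectra %*% B) %*% t(B), "OPS")
}

#' Spectral-ratio variables
#'
#' For every ordered wavelength pair `(j, k)`, `j != k`, forms the
#' per-sample ratio `column_j / column_k`. Applied after an additive-only
#' correction (LRC or OPS) this cancels the per-sample multiplicative
#' factor exactly: rows `a_i * s` all map to the same ratio values. Pairs
#' whose denominator magnitude falls below `denominator_floor` for any
#' calibration sample are dropped and reported; when correcting validation
#' spectra, pass the calibration pair list via `pairs` so the same
#' variables are produced.
#'
#' @param corrected additive-corrected matrix (samples x wavelengths).
#' @param wavelengths wavelength grid in nm.
#' @param denominator_floor minimum tolerated `|denominator|`; default
#'   `0.02 * max(abs(corrected))`. Additive-corrected spectra cross zero
#'   (OPS output is orthogonal to the baseline span by construction), and a
#'   ratio against a near-zero denominator is a pure noise amplifier whose
#'   scale dwarfs every informative variable in a scale-sensitive
#'   regression, so aggressive screening is the default.
#' @param pairs optional two-column integer matrix of (numerator,
#'   denominator) column indices to reuse; skips the floor filter.
#' @return An object of class `ratio_variable_set`: `pair_indices`
#'   (two-column matrix, lexicographic order), `values`
#'   (samples x pairs), `source_wavelengths`, `denominator_floor` and
#'   `n_dropped`.
#' @export
build_spectral_ratios <- function(corrected, wavelengths,
                                  denominator_floor = NULL, pairs = NULL) {
  corrected <- as_spectra_matrix(corrected)
  wavelengths <- check_wavelengths(wavelengths, ncol(corrected))
  p <- ncol(corrected)
  if (is.null(pairs)) {
    if (is.null(denominator_floor))
      denominator_floor <- 0.02 * max(abs(corrected))
    jj <- rep(seq_len(p), each = p)
    kk <- rep(seq_len(p), times = p)
    off <- jj != kk
    jj <- jj[off]; kk <- kk[off]
    ok_den <- apply(abs(corrected) >= denominator_floor, 2, all)
    keep <- ok_den[kk]
    n_dropped <- sum(!keep)
    if (!any(keep))
      stop("all ratio pairs dropped: every denominator falls below the floor")
    jj <- jj[keep]; kk <- kk[keep]
    pairs <- cbind(numerator = jj, denominator = kk)
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must be a two-column index matrix")
    if (is.null(denominator_floor)) denominator_floor <- 0
    n_dropped <- 0L
  }
  values <- corrected[, pairs[, 1], drop = FALSE] /
    corrected[, pairs[, 2], drop = FALSE]
  colnames(values) <- sprintf("%s/%s",
                              format(wavelengths[pairs[, 1]], trim = TRUE),
                              format(wavelengths[pairs[, 2]], trim = TRUE))
  structure(list(pair_indices = pairs, values = values,
                 source_wavelengths = wavelengths,
                 denominator_floor = denominator_floor,
                 n_dropped = n_dropped),
            class = "ratio_variable_set")
}

#' @export
print.ratio_variable_set <- function(x, ...) {
  cat(sprintf("<ratio_variable_set> %d samples x %d ordered pairs (%d dropped by floor %.3g)\n",
              nrow(x$values), nrow(x$pair_indices), x$n_dropped,
              x$denominator_floor))
  invisible(x)
}
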
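#' Modified optical path length estimation and correction (OPLECm)
#'
#' Estimates the per-sample multiplicative (path-length) factor `p_i` from
#' the calibration spectra and handles it through a dual-model prediction
#' rather than dividing it out. Under the wavelength-dependent additive
#' model, each spectrum is `x_i = p_i * (m + y_i * g) + baseline_i` with the
#' baseline in span `{1, lambda, lambda^2}`: after projecting that span out,
#' the spectra live in a two-dimensional subspace whose coordinates are
#' proportional to `(p_i, p_i * y_i)`. The estimator takes the rank-2 SVD of
#' the projected calibration spectra and solves, in least squares, for the
#' in-plane direction whose coordinate ratio reproduces the known
#' calibration reference values; the resulting `p` is normalized to unit
#' mean. Two PLS models are then trained — one predicting `p_i * y_i`, one
#' predicting `p_i` — and new samples are predicted as the ratio of the two
#' model outputs, which cancels the unknown path-length factor.
#'
#' If the estimated factors are numerically constant (scatter-free data)
#' the second model degenerates to the constant 1 and the prediction
#' reduces to plain PLS on the reference values.
#'
#' @param calib_spectra calibration spectra matrix (samples x wavelengths).
#' @param calib_reference calibration reference values (not constant).
#' @param n_lv latent variables for both internal PLS models.
#' @param wavelengths wavelength grid in nm.
#' @param degree polynomial degree of the projected-out baseline span.
#' @return An object of class `oplecm_model`: estimated `p`, the two PLS
#'   models, and the projection settings. Supports `predict()`.
#' @export
oplecm_correct <- function(calib_spectra, calib_reference, n_lv,
                           wavelengths, degree = 2L) {
  X <- as_spectra_matrix(calib_spectra)
  y <- as.numeric(calib_reference)
  n <- nrow(X)
  if (length(y) != n) stop("one reference value per calibration sample required")
  if (stats::sd(y) == 0)
    stop("calibration reference values are constant; OPLECm undefined")
  wavelengths <- check_wavelengths(wavelengths, ncol(X))

  B <- baseline_basis(wavelengths, degree)
  Z <- X - (X %*% B) %*% t(B)
  sv <- svd(Z, nu = 2L, nv = 0L)
  if (sv$d[1] <= 0) stop("projected spectra are zero; cannot estimate path factors")
  if (sv$d[2] <= 1e-12 * sv$d[1]) {
    # rank-1 subspace: a single in-plane direction, path factors are its scores
    p_hat <- sv$u[, 1] * sv$d[1]
  } else {
    S <- sv$u %*% diag(sv$d[1:2])
    # find m1, m2 with S m2 = diag(y) S m1: smallest singular direction of [S, -yS]
    A <- cbind(S, -y * S)
    v <- svd(A, nu = 0L, nv = 4L)$v[, 4]
    p_hat <- as.numeric(S %*% v[3:4])
  }
  if (abs(mean(p_hat)) <= 1e-12 * max(abs(p_hat)))
    stop("estimated path factors have zero mean; cannot normalize")
  p_hat <- p_hat / mean(p_hat)

  if (stats::sd(p_hat) < 1e-8) {
    p_hat <- rep(1, n)
    model1 <- fit_pls(X, y, n_lv)
    model2 <- NULL
  } else {
    model1 <- fit_pls(X, p_hat * y, n_lv)
    model2 <- fit_pls(X, p_hat, n_lv)
  }
  structure(list(p = p_hat, model1 = model1, model2 = model2,
                 n_lv = as.integer(n_lv), degree = degree,
                 wavelengths = wavelengths, method = "OPLECm",
                 estimated_scatter = p_hat),
            class = "oplecm_model")
}

#' Predict from an OPLECm dual model
#'
#' `y_hat = model1(X) / model2(X)`: the numerator predicts
#' `p * y`, the denominator `p`, and the ratio cancels the per-sample
#' path-length factor.
#'
#' @param object an [oplecm_correct()] model.
#' @param X new spectra matrix.
#' @param n_lv optional smaller component count.
#' @param p_tol predicted path factors below this tolerance raise an error
#'   (the ratio would blow up).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.oplecm_model <- function(object, X, n_lv = object$n_lv,
                                 p_tol = 1e-6, ...) {
  num <- predict(object$model1, X, n_lv = n_lv)
  den <- if (is.null(object$model2)) rep(1, length(num))
         else predict(object$model2, X, n_lv = n_lv)
  if (any(den < p_tol))
    stop(sprintf("predicted path factor below tolerance for sample(s) %s",
                 paste(which(den < p_tol), collapse = ", ")))
  num / den
}

# prediction matrix over all component counts (samples x n_lv)
oplecm_predict_path <- function(object, X) {
  num <- pls_predict_path(object$model1, X)
  if (is.null(object$model2)) return(num)
  # clamp degenerate path factors instead of erroring: inside cross-validation
  # a blown-up ratio should score badly, not abort the protocol
  den <- pmax(pls_predict_path(object$model2, X), 1e-6)
  num / den
}

#' @export
print.oplecm_model <- function(x, ...) {
  cat(sprintf("<oplecm_model> %d latent variables; path factors in [%.3f, %.3f]%s\n",
              x$n_lv, min(x$p), max(x$p),
              if (is.null(x$model2)) " (degenerate: constant)" else ""))
  invisible(x)
}
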
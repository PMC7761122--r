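#' Single-response partial least squares regression
#'
#' Mean-centered PLS1 with sequential deflation (NIPALS-equivalent scores,
#' weights and loadings), implemented with the kernel recurrence that
#' deflates only the covariance vector `X'y` so large variable matrices are
#' never copied per component. Regression coefficients on the original scale
#' are exposed for every component count up to `n_lv`, and predictions via
#' the coefficients coincide with sequential latent-variable reconstruction
#' to machine precision.
#'
#' @param X numeric matrix, samples x variables.
#' @param y numeric response vector.
#' @param n_lv number of latent variables; must not exceed
#'   `min(nrow(X) - 1, ncol(X))`. If the response covariance is exhausted
#'   earlier (rank-deficient systems) extraction stops and later components
#'   repeat the last informative one.
#' @return An object of class `pls_model`: centering means, weights `W`,
#'   loadings `P`, scores `TT`, y-loadings `q`, the coefficient vector for
#'   `n_lv` components and the full coefficient path (one column per
#'   component count).
#' @export
fit_pls <- function(X, y, n_lv) {
  X <- as_spectra_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (stats::sd(y) == 0) stop("response y is constant; PLS undefined")
  n_lv <- as.integer(n_lv)
  max_lv <- min(n - 1L, p)
  if (n_lv < 1L || n_lv > max_lv)
    stop(sprintf("n_lv must be between 1 and min(n - 1, p) = %d", max_lv))

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  yc <- y - y_mean

  # centering is folded into the products: for column-centered Xc and any
  # vector v with sum(v) = 0, crossprod(Xc, v) == crossprod(X, v), and
  # Xc %*% w == X %*% w - mean(X %*% w); X is never copied.
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  TT <- matrix(0, n, n_lv); q <- numeric(n_lv)
  s <- as.numeric(crossprod(X, yc))
  s0 <- sqrt(sum(s^2))
  m <- 0L
  for (a in seq_len(n_lv)) {
    ns <- sqrt(sum(s^2))
    if (ns <= 1e-14 * max(s0, 1)) break  # response covariance exhausted
    w <- s / ns
    t <- as.numeric(X %*% w)
    t <- t - mean(t)
    if (a > 1L) {
      # scores of the deflated matrix, plus a re-orthogonalization pass
      t <- t - TT[, 1:(a - 1L), drop = FALSE] %*%
        crossprod(P[, 1:(a - 1L), drop = FALSE], w)
      t <- t - TT[, 1:(a - 1L), drop = FALSE] %*%
        (crossprod(TT[, 1:(a - 1L), drop = FALSE], t) /
           colSums(TT[, 1:(a - 1L), drop = FALSE]^2))
      t <- as.numeric(t)
    }
    tt <- sum(t^2)
    if (tt <= 1e-28 * max(s0, 1)^2) break
    pv <- as.numeric(crossprod(X, t)) / tt
    qa <- sum(yc * t) / tt
    W[, a] <- w; P[, a] <- pv; TT[, a] <- t; q[a] <- qa
    s <- s - pv * (qa * tt)
    m <- a
  }
  if (m == 0L) stop("no usable latent variable could be extracted")

  # coefficients for every component count: B_a = W_a (P_a' W_a)^{-1} q_a
  R <- crossprod(P[, 1:m, drop = FALSE], W[, 1:m, drop = FALSE])
  coef_path <- matrix(0, p, n_lv)
  for (a in seq_len(m)) {
    coef_path[, a] <- W[, 1:a, drop = FALSE] %*%
      solve(R[1:a, 1:a, drop = FALSE], q[1:a])
  }
  if (m < n_lv) coef_path[, (m + 1L):n_lv] <- coef_path[, m]

  structure(list(n_lv = n_lv, n_components = m,
                 x_mean = x_mean, y_mean = y_mean,
                 weights = W[, 1:m, drop = FALSE],
                 loadings = P[, 1:m, drop = FALSE],
                 scores = TT[, 1:m, drop = FALSE],
                 y_loadings = q[1:m],
                 coefficients = coef_path[, n_lv],
                 coef_path = coef_path),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' `y_hat = (X - x_mean) %*% coefficients + y_mean`.
#'
#' @param object a [fit_pls()] model.
#' @param X new variable matrix with the training column count.
#' @param n_lv optional smaller component count to predict with.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, X, n_lv = object$n_lv, ...) {
  X <- as_spectra_matrix(X)
  if (ncol(X) != length(object$x_mean))
    stop(sprintf("X has %d columns; model was trained on %d",
                 ncol(X), length(object$x_mean)))
  if (n_lv < 1L || n_lv > object$n_lv)
    stop("n_lv outside the fitted component range")
  b <- object$coef_path[, n_lv]
  drop(X %*% b) + (object$y_mean - sum(object$x_mean * b))
}

# predictions for every component count at once (samples x n_lv)
pls_predict_path <- function(object, X) {
  X <- as_spectra_matrix(X)
  offset <- object$y_mean - as.numeric(object$x_mean %*% object$coef_path)
  sweep(X %*% object$coef_path, 2, offset, `+`)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables (%d extracted), %d variables\n",
              x$n_lv, x$n_components, length(x$x_mean)))
  invisible(x)
}

#' Determination coefficient with selectable denominator convention
#'
#' `"standard"` (default) uses the conventional total sum of squares
#' `sum((y - mean(y))^2)`; `"as_printed"` uses `sum((y_hat - mean(y))^2)`,
#' a variant sometimes printed in application papers that yields 0 for
#' shrunk-but-correlated predictions. Both are exposed so either reading can
#' be reproduced; they agree at perfect fit.
#'
#' @param y_hat predictions.
#' @param y observed values.
#' @param convention `"standard"` or `"as_printed"`.
#' @return The determination coefficient; `NaN` (flagged not-a-value) when
#'   the denominator is zero.
#' @export
r2_metric <- function(y_hat, y, convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  if (length(y_hat) != length(y)) stop("y_hat and y must have equal length")
  if (length(y) < 2L) stop("need at least two observations")
  ym <- mean(y)
  denom <- if (convention == "standard") sum((y - ym)^2) else sum((y_hat - ym)^2)
  if (denom == 0) return(NaN)
  1 - sum((y_hat - y)^2) / denom
}

#' Root mean square error
#'
#' @inheritParams r2_metric
#' @return `sqrt(mean((y_hat - y)^2))`.
#' @export
rmse_metric <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("y_hat and y must have equal length")
  sqrt(mean((y_hat - y)^2))
}
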
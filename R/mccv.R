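#' Monte Carlo cross-validation for latent-variable selection
#'
#' Repeats a seeded random calibration / hold-out split `n_reps` times; per
#' repetition a PLS model with the largest requested component count is
#' fitted on the calibration part and the hold-out samples are predicted at
#' every component count. Squared errors are pooled over all repetitions:
#' with `pooling = "pooled"` (default) `RMSEcv` divides the pooled squared
#' error by the total number of predictions made; `pooling = "as_printed"`
#' divides by `N * n` with `n` the full sample count, the literal reading of
#' the printed cross-validation formula (which understates the error since
#' only a fraction of samples is predicted per repetition). `R2cv` is
#' computed on the pooled predictions with the standard total-sum-of-squares
#' denominator.
#'
#' The chosen component count is the smallest one attaining the minimum
#' `RMSEcv`; near-ties (relative difference below `1e-8`) are resolved
#' toward fewer components so that rank-deficient noise-free systems select
#' their true dimension rather than an arbitrary float-level minimum.
#'
#' @param X numeric matrix, samples x variables.
#' @param y numeric response.
#' @param lv_range integer vector of candidate component counts
#'   (default `1:20`); truncated with a warning if infeasible for the split.
#' @param n_reps number of Monte Carlo repetitions (default 100).
#' @param split_fraction fraction of samples in each calibration part.
#' @param seed integer seed; the report is reproducible given the seed.
#' @param pooling `"pooled"` or `"as_printed"` (see Details).
#' @param fit_fun model constructor `function(X, y, n_lv)`; defaults to
#'   [fit_pls()]. Any model whose `predict` path spans all component counts
#'   can be plugged in (used for the dual-model path-length method).
#' @param predict_path_fun `function(model, X)` returning an
#'   n x max(lv) prediction matrix; defaults to the PLS coefficient path.
#' @return An object of class `cv_report`: a per-LV table (`lv`, `rmsecv`,
#'   `r2cv`), `chosen_lv`, and the protocol parameters.
#' @export
mccv <- function(X, y, lv_range = 1:20, n_reps = 100L, split_fraction = 0.8,
                 seed = NULL, pooling = c("pooled", "as_printed"),
                 fit_fun = fit_pls, predict_path_fun = pls_predict_path) {
  pooling <- match.arg(pooling)
  X <- as_spectra_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  n_train <- floor(split_fraction * n)
  if (n_train < 2L || n_train >= n)
    stop("split_fraction leaves too few calibration or hold-out samples")
  max_feasible <- min(n_train - 1L, ncol(X))
  lv_range <- sort(unique(as.integer(lv_range)))
  if (max(lv_range) > max_feasible) {
    warning(sprintf("lv_range truncated to %d (limited by split size / variables)",
                    max_feasible))
    lv_range <- lv_range[lv_range <= max_feasible]
    if (!length(lv_range)) stop("no feasible component count")
  }
  A <- max(lv_range)

  rep_seeds <- derive_seeds(seed, n_reps)
  sse <- numeric(A)
  n_pred <- 0L
  y_pool <- numeric(0)
  for (r in seq_len(n_reps)) {
    tr <- with_seed(rep_seeds[[r]], sort(sample.int(n, n_train)))
    te <- setdiff(seq_len(n), tr)
    model <- fit_fun(X[tr, , drop = FALSE], y[tr], A)
    pred <- predict_path_fun(model, X[te, , drop = FALSE])
    err <- (pred - y[te])^2
    sse <- sse + colSums(err)
    n_pred <- n_pred + length(te)
    y_pool <- c(y_pool, y[te])
  }
  denom_n <- if (pooling == "pooled") n_pred else n_reps * n
  rmsecv <- sqrt(sse / denom_n)
  r2cv <- 1 - sse / sum((y_pool - mean(y_pool))^2)

  rmse_sel <- rmsecv[lv_range]
  best <- min(rmse_sel)
  chosen_lv <- lv_range[which(rmse_sel <= best * (1 + 1e-8) + 1e-15)[1]]

  structure(list(table = data.frame(lv = lv_range, rmsecv = rmse_sel,
                                    r2cv = r2cv[lv_range]),
                 chosen_lv = chosen_lv, n_reps = n_reps,
                 split_fraction = split_fraction, pooling = pooling,
                 n_samples = n, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  i <- match(x$chosen_lv, x$table$lv)
  cat(sprintf("<cv_report> %d Monte Carlo repetitions (%d%% calibration)\n",
              x$n_reps, round(100 * x$split_fraction)))
  cat(sprintf("  chosen LV = %d: RMSEcv = %.4g, R2cv = %.4f\n",
              x$chosen_lv, x$table$rmsecv[i], x$table$r2cv[i]))
  invisible(x)
}

#' Plot RMSEcv against the number of latent variables
#'
#' @param x a [mccv()] report.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(x$table$lv, x$table$rmsecv, type = "b", pch = 16,
                 xlab = "Latent variables", ylab = "RMSEcv (%)", ...)
  i <- match(x$chosen_lv, x$table$lv)
  graphics::points(x$chosen_lv, x$table$rmsecv[i], col = 2, pch = 8, cex = 1.4)
  invisible(x)
}
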
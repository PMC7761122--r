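#' Configuration for competitive adaptive reweighted sampling
#'
#' @param n_iterations number of Monte Carlo iterations `N` (default 50).
#' @param mc_sample_fraction fraction of samples drawn per iteration for
#'   fitting the weighting model (default 0.8).
#' @param n_lv latent variables of the internal PLS fits, normally fixed
#'   from a prior cross-validation.
#' @param cv_folds folds of the internal subset-scoring cross-validation
#'   (default 5).
#' @param seed integer seed.
#' @return An object of class `cars_config`.
#' @export
cars_config <- function(n_iterations = 50L, mc_sample_fraction = 0.8,
                        n_lv = 10L, cv_folds = 5L, seed = NULL) {
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 2L) stop("n_iterations must be >= 2")
  if (mc_sample_fraction <= 0 || mc_sample_fraction >= 1)
    stop("mc_sample_fraction must lie in (0, 1)")
  structure(list(n_iterations = n_iterations,
                 mc_sample_fraction = mc_sample_fraction,
                 n_lv = as.integer(n_lv), cv_folds = as.integer(cv_folds),
                 seed = seed),
            class = "cars_config")
}

#' Exponentially decreasing retention schedule
#'
#' The fraction of variables retained at iteration `i` of `N` follows
#' `r_i = a * exp(-k * i)` with the boundary conditions `r_1 = 1` (all `p`
#' variables enter) and `r_N = 2 / p` (two survive the last iteration),
#' giving `k = log(p / 2) / (N - 1)` and `a = exp(k)`.
#'
#' @param i iteration, `1 <= i <= N`.
#' @param N total iterations (`>= 2`).
#' @param p number of variables (`>= 3`).
#' @return Fraction of variables retained (vectorized over `i`).
#' @export
edf_ratio <- function(i, N, p) {
  if (N < 2) stop("N must be >= 2")
  if (p < 3) stop("p must be >= 3")
  if (any(i < 1) || any(i > N)) stop("iteration i must lie in [1, N]")
  k <- log(p / 2) / (N - 1)
  exp(k) * exp(-k * i)
}

#' Adaptive reweighted sampling
#'
#' Weighted sampling without replacement: `n_keep` variables are drawn with
#' probability proportional to their (non-negative) weights, so strong
#' regression coefficients compete for survival while zero-weight variables
#' are never selected. If fewer than `n_keep` weights are positive, all
#' positive-weight variables are kept with a warning.
#'
#' @param weights non-negative weight vector.
#' @param n_keep number of variables to retain.
#' @param seed integer seed.
#' @return Sorted integer vector of selected indices.
#' @export
adaptive_reweighted_sample <- function(weights, n_keep, seed = NULL) {
  weights <- as.numeric(weights)
  if (any(weights < 0) || anyNA(weights)) stop("weights must be non-negative")
  pos <- which(weights > 0)
  if (length(pos) < n_keep) {
    warning(sprintf("only %d positive weights for n_keep = %d; keeping all of them",
                    length(pos), n_keep))
    return(pos)
  }
  if (n_keep == length(weights)) return(seq_along(weights))
  with_seed(seed, sort(sample(seq_along(weights), n_keep, prob = weights)))
}

# pooled K-fold cross-validated RMSE of a PLS model on fixed folds
kfold_rmse <- function(X, y, n_lv, folds) {
  sse <- 0
  for (f in unique(folds)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    lv <- min(n_lv, length(tr) - 1L, ncol(X))
    model <- fit_pls(X[tr, , drop = FALSE], y[tr], lv)
    sse <- sse + sum((predict(model, X[te, , drop = FALSE]) - y[te])^2)
  }
  sqrt(sse / length(y))
}

#' Run competitive adaptive reweighted sampling
#'
#' At each of `N` iterations a Monte Carlo subsample of rows is drawn, a PLS
#' model is fitted on the currently retained variables, and the absolute
#' regression coefficients become sampling weights. The retained count is
#' capped by the exponentially decreasing schedule [edf_ratio()] and the
#' survivors are drawn by [adaptive_reweighted_sample()]. Every iteration's
#' retained subset is scored by `cv_folds`-fold cross-validated RMSE on
#' fixed folds (so iterations are comparable); the winner is the subset with
#' minimum RMSECV, ties resolved toward fewer variables, then the earlier
#' iteration. Fully seeded and reproducible.
#'
#' @param X variable matrix (wavelengths or ratio variables), `>= 3` columns.
#' @param y response vector (not constant).
#' @param config a [cars_config()].
#' @return An object of class `cars_result`: EDF constants, per-iteration
#'   retained index sets and `rmsecv` trajectory, `best_iteration`,
#'   `selected_indices`.
#' @export
run_cars <- function(X, y, config = cars_config()) {
  stopifnot(inherits(config, "cars_config"))
  X <- as_spectra_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 3L) stop("CARS needs at least 3 variables")
  if (stats::sd(y) == 0) stop("response y is constant")
  N <- config$n_iterations
  n_mc <- max(2L, floor(config$mc_sample_fraction * n))

  seeds <- derive_seeds(config$seed, 2L * N + 1L)
  folds <- with_seed(seeds[[2L * N + 1L]],
                     sample(rep_len(seq_len(config$cv_folds), n)))

  k <- log(p / 2) / (N - 1)
  retained <- seq_len(p)
  sets <- vector("list", N)
  rmsecv <- numeric(N)
  lv_used <- integer(N)
  for (i in seq_len(N)) {
    rows <- with_seed(seeds[[2L * i - 1L]], sort(sample.int(n, n_mc)))
    lv <- min(config$n_lv, length(retained), n_mc - 1L)
    if (lv < config$n_lv && i == 1L)
      message(sprintf("CARS: n_lv reduced to %d (subset size limit)", lv))
    model <- fit_pls(X[rows, retained, drop = FALSE], y[rows], lv)
    w <- abs(model$coefficients)
    w <- w / sum(w)
    n_keep <- min(length(retained), max(2L, round(edf_ratio(i, N, p) * p)))
    keep <- adaptive_reweighted_sample(w, n_keep, seed = seeds[[2L * i]])
    retained <- retained[keep]
    sets[[i]] <- retained
    lv_i <- min(config$n_lv, length(retained))
    lv_used[i] <- lv_i
    rmsecv[i] <- kfold_rmse(X[, retained, drop = FALSE], y, lv_i, folds)
  }
  best <- min(rmsecv)
  cand <- which(rmsecv <= best * (1 + 1e-12))
  sizes <- lengths(sets[cand])
  cand <- cand[sizes == min(sizes)]
  best_iteration <- cand[1]

  structure(list(edf_a = exp(k), edf_k = k,
                 retained_sets = sets, rmsecv = rmsecv, lv_used = lv_used,
                 best_iteration = best_iteration,
                 selected_indices = sets[[best_iteration]],
                 n_variables = p, config = config),
            class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result> %d iterations over %d variables\n",
              length(x$rmsecv), x$n_variables))
  cat(sprintf("  best iteration %d: %d variables, RMSECV = %.4g\n",
              x$best_iteration, length(x$selected_indices),
              x$rmsecv[x$best_iteration]))
  invisible(x)
}

#' Plot the CARS RMSECV trajectory and retained-variable counts
#'
#' @param x a [run_cars()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cars_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(lengths(x$retained_sets), type = "s",
                 xlab = "Iteration", ylab = "Variables retained", ...)
  graphics::plot(x$rmsecv, type = "b", pch = 16,
                 xlab = "Iteration", ylab = "RMSECV")
  graphics::abline(v = x$best_iteration, col = 2, lty = 2)
  invisible(x)
}
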
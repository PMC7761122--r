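test_that("full-rank PLS reproduces ordinary least squares", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(15:40, 1)
      p <- sample(2:8, 1)
      X <- matrix(stats::rnorm(n * p), n)
      y <- drop(X %*% stats::rnorm(p)) + stats::rnorm(n, sd = 0.2)
    })
    model <- fit_pls(X, y, p)
    Z <- cbind(1, X)
    ols_pred <- drop(Z %*% solve(crossprod(Z), crossprod(Z, y)))
    expect_equal(predict(model, X), ols_pred, tolerance = 1e-8)
  }
})

test_that("single-variable PLS equals simple regression", {
  withr::with_seed(2, {
    x <- stats::rnorm(30)
    y <- 2 + 3 * x + stats::rnorm(30, sd = 0.1)
  })
  model <- fit_pls(matrix(x), y, 1)
  expect_equal(model$coefficients, stats::cov(x, y) / stats::var(x),
               tolerance = 1e-12)
})

test_that("coefficient predictions equal sequential score reconstruction", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(40 * 12), 40)
    y <- stats::rnorm(40)
  })
  model <- fit_pls(X, y, 6)
  recon <- model$y_mean + drop(model$scores %*% model$y_loadings)
  expect_equal(predict(model, X), recon, tolerance = 1e-10)
})

test_that("training error is non-increasing in the number of components", {
  withr::with_seed(4, {
    X <- matrix(stats::rnorm(50 * 15), 50)
    y <- drop(X %*% stats::rnorm(15)) + stats::rnorm(50)
  })
  model <- fit_pls(X, y, 10)
  rmse_by_lv <- sapply(1:10, function(a)
    rmse_metric(predict(model, X, n_lv = a), y))
  expect_true(all(diff(rmse_by_lv) <= 1e-12))
})

test_that("PLS preconditions are enforced and prediction identities hold", {
  X <- matrix(stats::rnorm(20 * 5), 20)
  expect_error(fit_pls(X, rep(1, 20), 2), "constant")
  expect_error(fit_pls(X, stats::rnorm(20), 6), "n_lv")

  withr::with_seed(5, {
    y <- drop(X %*% stats::rnorm(5))
  })
  model <- fit_pls(X, y, 5)
  # noise-free exactly-fit system interpolates its training data
  expect_equal(predict(model, X), y, tolerance = 1e-8)
  # the training-mean spectrum predicts the training-mean response
  expect_equal(predict(model, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-10)
  # duplicated rows give identical predictions
  two <- predict(model, X[c(3, 3), ])
  expect_identical(two[1], two[2])
  expect_error(predict(model, X[, 1:3]), "columns")
})

test_that("the determination coefficient honors both denominator conventions", {
  y <- c(1, 2, 3); y_hat <- c(1.5, 2, 2.5)
  expect_equal(r2_metric(y_hat, y, "as_printed"), 0)
  expect_equal(r2_metric(y_hat, y, "standard"), 0.75)
  expect_equal(r2_metric(y, y, "standard"), 1)
  expect_equal(r2_metric(y, y, "as_printed"), 1)
  expect_true(is.nan(r2_metric(rep(2, 3), rep(2, 3))))
  expect_equal(r2_metric(rep(2, 3), y, "standard"), 0)
  expect_equal(rmse_metric(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse_metric(c(2, 3), c(1, 2)), 1)
})
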
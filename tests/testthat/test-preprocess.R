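wl <- tiny_grid()

test_that("Savitzky-Golay smoothing preserves low-order polynomials and denoises", {
  u <- seq_along(wl)
  quad <- 3 + 0.5 * u - 0.01 * u^2
  expect_equal(as.numeric(sg_smooth(quad)), quad, tolerance = 1e-10)
  expect_equal(as.numeric(sg_smooth(rep(2, 46))), rep(2, 46))

  noisy <- quad + withr::with_seed(4, stats::rnorm(46, sd = 0.3))
  smoothed <- as.numeric(sg_smooth(noisy))
  expect_lt(sum((smoothed - quad)^2), sum((noisy - quad)^2))

  expect_error(sg_smooth(quad, window = 8), "odd")
  expect_error(sg_smooth(quad[1:5], window = 9), "length")
})

test_that("NOR scales rows to unit norm and is scale invariant", {
  res <- normalize_nor(matrix(c(3, 4), 1))
  expect_equal(as.numeric(res$corrected), c(0.6, 0.8))
  expect_equal(normalize_nor(res$corrected)$corrected, res$corrected)
  x <- matrix(stats::runif(46, 0.1, 1), 1)
  expect_equal(normalize_nor(5 * x)$corrected, normalize_nor(x)$corrected)
  expect_error(normalize_nor(matrix(0, 1, 5)), "zero")
})

test_that("first derivative removes offsets and tracks slopes", {
  const <- matrix(5, 1, length(wl))
  expect_equal(as.numeric(first_derivative(const, wl)$corrected),
               rep(0, length(wl)))
  lin <- matrix(wl, 1)
  expect_equal(as.numeric(first_derivative(lin, wl)$corrected),
               rep(1, length(wl)), tolerance = 1e-10)
  x <- random_spectra(3, wl, seed = 5)
  expect_equal(first_derivative(x + 7, wl)$corrected,
               first_derivative(x, wl)$corrected, tolerance = 1e-10)
})

test_that("detrend annihilates polynomial baselines of its degree", {
  quad <- matrix(3 + 0.5 * wl - 0.01 * wl^2, 1)
  expect_equal(as.numeric(detrend(quad, wl)$corrected), rep(0, length(wl)),
               tolerance = 1e-8)
  x <- random_spectra(4, wl, seed = 6)
  resid <- detrend(x, wl)$corrected
  for (basis_vec in list(rep(1, length(wl)), wl, wl^2)) {
    expect_equal(as.numeric(resid %*% basis_vec) /
                   sqrt(sum(basis_vec^2)) / max(abs(x)),
                 rep(0, 4), tolerance = 1e-8)
  }
  centered <- detrend(x, wl, degree = 0)$corrected
  expect_equal(centered, x - rowMeans(x), tolerance = 1e-12)
})

test_that("SNV standardizes each row and ignores affine scatter", {
  res <- snv(matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(res$corrected), c(-1, 0, 1))
  x <- random_spectra(5, wl, seed = 7)
  out <- snv(x)$corrected
  expect_equal(rowMeans(out), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(out, 1, stats::sd), rep(1, 5), tolerance = 1e-12)
  expect_error(snv(matrix(1, 1, 5)), "zero-variance")
})

test_that("MSC inverts an exact affine transform of the reference", {
  m <- as.numeric(random_spectra(1, wl, seed = 8))
  res <- msc(matrix(2 * m + 3, 1), reference = m)
  expect_equal(as.numeric(res$corrected), m, tolerance = 1e-10)
  expect_equal(res$estimated_scatter$a, 2, tolerance = 1e-10)
  expect_equal(res$estimated_scatter$b, 3, tolerance = 1e-10)

  same <- msc(matrix(m, 1), reference = m)
  expect_equal(as.numeric(same$corrected), m, tolerance = 1e-12)
  expect_equal(same$estimated_scatter$a, 1, tolerance = 1e-12)
  expect_equal(same$estimated_scatter$b, 0, tolerance = 1e-10)
})

test_that("PQN cancels pure multiplicative scatter", {
  x <- random_spectra(4, wl, seed = 9) + 0.5
  expect_equal(pqn(3 * x)$corrected, pqn(x)$corrected, tolerance = 1e-12)

  ref_in <- abs(as.numeric(random_spectra(1, wl, seed = 10))) + 0.5
  res <- pqn(matrix(ref_in, 1))
  expect_equal(as.numeric(res$corrected), ref_in / sum(ref_in),
               tolerance = 1e-12)

  s <- ref_in
  batch <- outer(c(0.5, 1, 2, 7), s)
  out <- pqn(batch)$corrected
  expect_equal(out[1, ], out[4, ], tolerance = 1e-12)
  expect_equal(max(apply(out, 2, stats::sd)), 0, tolerance = 1e-12)
})

test_that("LRC removes only the additive offset", {
  m <- as.numeric(random_spectra(1, wl, seed = 11))
  res <- lrc_correct(matrix(1.5 * m + 0.7, 1), reference = m)
  expect_equal(as.numeric(res$corrected), 1.5 * m, tolerance = 1e-10)
  expect_equal(res$estimated_scatter$b, 0.7, tolerance = 1e-10)
  same <- lrc_correct(matrix(m, 1), reference = m)
  expect_equal(as.numeric(same$corrected), m, tolerance = 1e-12)
})

test_that("OPS projects exactly onto the complement of the baseline span", {
  quad <- matrix(3 + 0.5 * wl - 0.01 * wl^2, 1)
  expect_equal(max(abs(ops_project(quad, wl)$corrected)), 0, tolerance = 1e-8)
  x <- random_spectra(4, wl, seed = 12)
  once <- ops_project(x, wl)$corrected
  expect_equal(ops_project(once, wl)$corrected, once, tolerance = 1e-10)
  for (basis_vec in list(rep(1, length(wl)), wl, wl^2)) {
    expect_equal(as.numeric(once %*% basis_vec) /
                   sqrt(sum(basis_vec^2)) / max(abs(x)),
                 rep(0, 4), tolerance = 1e-8)
  }
})

test_that("ratio variables cancel multiplicative factors and enumerate ordered pairs", {
  s <- c(1, 2, 4)
  batch <- outer(c(0.5, 1, 3), s)
  rat <- build_spectral_ratios(batch, c(650, 700, 750))
  expect_equal(nrow(rat$pair_indices), 6)
  expect_false(any(rat$pair_indices[, 1] == rat$pair_indices[, 2]))
  # lexicographic pair order
  ord <- order(rat$pair_indices[, 1], rat$pair_indices[, 2])
  expect_identical(ord, seq_len(6L))
  for (i in seq_len(6)) {
    expect_equal(unname(rat$values[, i]),
                 rep(s[rat$pair_indices[i, 1]] / s[rat$pair_indices[i, 2]], 3),
                 tolerance = 1e-12)
  }

  # denominator floor drops pairs, and dropping everything is an error
  withfloor <- build_spectral_ratios(cbind(batch, 1e-9), c(650, 700, 750, 800),
                                     denominator_floor = 1e-6)
  expect_equal(withfloor$n_dropped, 3)
  expect_false(any(withfloor$pair_indices[, 2] == 4))
  expect_true(any(withfloor$pair_indices[, 1] == 4))
  expect_error(build_spectral_ratios(matrix(1e-9, 2, 3), c(1, 2, 3),
                                     denominator_floor = 1),
               "dropped")
})

test_that("SNV, MSC and PQN are invariant under the constant-offset scatter transform", {
  x <- random_spectra(6, wl, seed = 13) + 0.5
  ref <- colMeans(x)
  for (seed in 1:10) {
    ab <- withr::with_seed(seed, c(stats::runif(1, 0.3, 3),
                                   stats::runif(1, -0.5, 0.5)))
    y <- ab[1] * x + ab[2]
    expect_equal(snv(y)$corrected, snv(x)$corrected, tolerance = 1e-9)
    expect_equal(msc(y, reference = ref)$corrected,
                 msc(x, reference = ref)$corrected, tolerance = 1e-9)
    # PQN removes pure scaling
    expect_equal(pqn(ab[1] * x)$corrected, pqn(x)$corrected, tolerance = 1e-9)
  }
})

test_that("ratios after OPS are identical across samples sharing an ideal spectrum", {
  ideal <- matrix(rep(as.numeric(random_spectra(1, wl, seed = 14)) + 0.5,
                      each = 12), 12)
  sc <- withr::with_seed(15, scatter_params(
    a = stats::runif(12, 0.7, 1.3), b = stats::runif(12, -0.2, 0.2),
    c = stats::runif(12, -0.2, 0.2) / 1100,
    d = stats::runif(12, -0.2, 0.2) / 1100^2))
  obs <- apply_scatter_effects(ideal, sc, wl)
  z <- ops_project(obs, wl)$corrected
  rat <- build_spectral_ratios(z, wl, denominator_floor = 1e-3 * max(abs(z)))
  spread <- apply(rat$values, 2, function(col) diff(range(col)))
  expect_lt(max(spread / pmax(1, abs(colMeans(rat$values)))), 1e-8)
})

test_that("LRC-SR ratio variables outperform raw wavelengths in univariate correlation", {
  cfg <- synthetic_config()
  wins <- 0L
  n_rep <- 100L
  for (seed in seq_len(n_rep)) {
    gen <- generate_dataset(cfg, seed = 1000 + seed)
    sm <- sg_smooth(gen$dataset$spectra)
    y <- gen$dataset$reference
    r_raw <- max(abs(univariate_correlation(sm, y)), na.rm = TRUE)
    rat <- build_spectral_ratios(lrc_correct(sm)$corrected,
                                 gen$dataset$wavelengths)
    r_sr <- max(abs(univariate_correlation(rat$values, y)), na.rm = TRUE)
    wins <- wins + (r_sr > r_raw)
  }
  expect_gte(wins / n_rep, 0.95)
})
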
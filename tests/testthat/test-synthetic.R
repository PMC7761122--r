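test_that("component bands peak at their centers and are deterministic", {
  cfg <- synthetic_config(band_centers = c(975, 975, 740),
                          band_widths = c(30, 30, 20),
                          band_weights = c(1, 1, 1),
                          informative_band_indices = integer(0),
                          juiciness_slopes = c(0, 0, 0),
                          wavelength_step = 5)
  comps <- generate_component_bands(cfg)
  expect_equal(cfg$wavelengths[which.max(comps[1, ])], 975)
  expect_equal(max(comps[1, ]), 1)
  expect_identical(comps[1, ], comps[2, ])

  bad <- synthetic_config(band_centers = c(640, 740),
                          band_widths = c(10, 10), band_weights = c(1, 1),
                          informative_band_indices = integer(0),
                          juiciness_slopes = c(0, 0))
  expect_error(generate_component_bands(bad), "640")
})

test_that("identity scatter with zero noise reproduces the ideal spectra", {
  gen <- generate_dataset(identity_config(), seed = 3)
  expect_equal(unname(gen$dataset$spectra), unname(gen$truth$ideal_spectra),
               tolerance = 1e-12)
})

test_that("generation is bit-reproducible given config and seed", {
  cfg <- synthetic_config(n_samples = 30L, n_days = 3L)
  g1 <- generate_dataset(cfg, seed = 11)
  g2 <- generate_dataset(cfg, seed = 11)
  expect_identical(g1$dataset$spectra, g2$dataset$spectra)
  expect_identical(g1$truth$scatter, g2$truth$scatter)
  expect_identical(g1$truth$juiciness, g2$truth$juiciness)
  g3 <- generate_dataset(cfg, seed = 12)
  expect_false(identical(g1$dataset$spectra, g3$dataset$spectra))
})

test_that("under the constant-offset model each observed spectrum is an affine image of its ideal", {
  cfg <- synthetic_config(n_samples = 25L, n_days = 5L, scatter_model = "EQ3",
                          noise_sd = 0)
  gen <- generate_dataset(cfg, seed = 5)
  obs <- gen$dataset$spectra
  ideal <- gen$truth$ideal_spectra
  sc <- gen$truth$scatter
  for (i in seq_len(nrow(obs))) {
    fit <- stats::lm.fit(cbind(1, ideal[i, ]), obs[i, ])
    expect_equal(unname(fit$coefficients[2]), sc$a[i], tolerance = 1e-9)
    expect_equal(unname(fit$coefficients[1]), sc$b[i], tolerance = 1e-9)
  }
  expect_true(all(sc$c == 0) && all(sc$d == 0))
})

test_that("apply_scatter_effects implements the additive/multiplicative formula", {
  wl <- tiny_grid()
  p <- length(wl)
  x <- matrix(seq(0.5, 1.5, length.out = p), 1)
  id <- scatter_params(1, 0)
  expect_equal(apply_scatter_effects(x, id, wl), x)

  zero <- matrix(0, 1, p)
  expect_equal(as.numeric(apply_scatter_effects(zero, scatter_params(2, 5), wl)),
               rep(5, p))
  shifted <- apply_scatter_effects(x, scatter_params(1, 0, c = 1), wl)
  expect_equal(as.numeric(shifted - x), wl)
  expect_error(scatter_params(c(1, -0.5), 0), "positive")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(juiciness_range = c(-5, 50)), "juiciness_range")
  expect_error(synthetic_config(multiplicative_range = c(0, 1.3)), "positive")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(wavelength_start = 1100, wavelength_stop = 650),
               "increasing")
})

test_that("the informative band's peak column correlates perfectly with juiciness absent scatter", {
  gen <- generate_dataset(identity_config(), seed = 21)
  ds <- gen$dataset
  for (j in gen$truth$informative_wavelength_indices) {
    expect_equal(stats::cor(ds$spectra[, j], ds$reference), 1, tolerance = 1e-8)
  }
})

test_that("wavelength-dependent scatter strictly degrades the raw correlation", {
  for (seed in 1:20) {
    clean <- generate_dataset(identity_config(), seed = seed)
    messy <- generate_dataset(synthetic_config(noise_sd = 0), seed = seed)
    j <- clean$truth$informative_wavelength_indices[1]
    r_clean <- abs(stats::cor(clean$dataset$spectra[, j],
                              clean$dataset$reference))
    r_messy <- abs(stats::cor(messy$dataset$spectra[, j],
                              messy$dataset$reference))
    expect_lt(r_messy, r_clean)
  }
})
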
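test_that("transmittance follows the dark/white normalization", {
  expect_equal(compute_transmittance(c(5, 7), c(5, 7), c(10, 14)), c(0, 0))
  expect_equal(compute_transmittance(c(10, 14), c(5, 7), c(10, 14)), c(100, 100))
  expect_equal(compute_transmittance(150, 100, 200), 50)
  expect_error(compute_transmittance(1, 2, 2, wavelengths = 700), "700")
})

test_that("transmittance/absorbance conversion is exact and invertible", {
  wl <- tiny_grid()
  tds <- spectral_dataset(wl, matrix(c(100, 10, 1)[1 + (seq_along(wl) %% 3)], 1),
                          mode = "transmittance_pct")
  ads <- transmittance_to_absorbance(tds)
  expect_equal(unname(ads$spectra[1, 1:3]), c(1, 2, 0))

  withr::with_seed(8, {
    t_mat <- matrix(stats::runif(5 * length(wl), 0.5, 99), 5)
  })
  ds <- spectral_dataset(wl, t_mat, mode = "transmittance_pct")
  round_trip <- absorbance_to_transmittance(transmittance_to_absorbance(ds))
  expect_equal(round_trip$spectra, ds$spectra, tolerance = 1e-12)

  zero <- spectral_dataset(wl, matrix(0, 1, length(wl)),
                           mode = "transmittance_pct")
  expect_error(transmittance_to_absorbance(zero), "non-positive")
  expect_error(transmittance_to_absorbance(ads), "not in transmittance mode")
})

test_that("juiciness reference follows the printed weight-pair formula", {
  expect_equal(compute_juiciness(1.0, 1.2), 20)
  expect_equal(compute_juiciness(3.3, 3.3), 0)
  expect_equal(compute_juiciness(2.0, 1.5), -25)
  expect_equal(compute_juiciness(2.0, 1.5, sign_convention = "mass_loss"), 25)
  expect_error(compute_juiciness(0, 1), "positive")
})

test_that("replicate averaging reduces each group to its mean", {
  row <- seq(1, 2, length.out = 5)
  three <- rbind(row, row, row)
  expect_equal(unname(average_replicates(three, c("a", "a", "a"))[1, ]), row)
  mid <- average_replicates(rbind(rep(0, 4), rep(2, 4)), c("s", "s"))
  expect_equal(unname(mid[1, ]), rep(1, 4))
  single <- average_replicates(matrix(row, 1), "only")
  expect_equal(unname(single[1, ]), row)
})

test_that("the day-stratified split reproduces the 100/27 protocol", {
  n <- 9 * 13 + 10
  day <- rep(1:10, times = c(rep(13, 9), 10))
  ds <- spectral_dataset(tiny_grid(), matrix(stats::rnorm(n * 46), n), day = day)
  sp <- split_calibration_validation(ds, per_day = 10, seed = 1)
  expect_length(sp$calibration, 100)
  expect_length(sp$validation, 27)
  expect_length(intersect(sp$calibration, sp$validation), 0)

  sp2 <- split_calibration_validation(ds, per_day = 10, seed = 1)
  expect_identical(sp, sp2)
  expect_error(split_calibration_validation(ds, per_day = 11), "10")

  # a day fully consumed by calibration contributes no validation samples
  ds4 <- dataset_subset(ds, which(day <= 2))
  sp4 <- split_calibration_validation(ds4, per_day = 13, seed = 2)
  expect_length(sp4$validation, 0)
})

test_that("splits are exhaustive and disjoint for all seeds", {
  day <- rep(1:5, each = 8)
  ds <- spectral_dataset(tiny_grid(), matrix(stats::rnorm(40 * 46), 40),
                         day = day)
  for (seed in 1:100) {
    sp <- split_calibration_validation(ds, per_day = 5, seed = seed)
    expect_identical(sort(c(sp$calibration, sp$validation)), 1:40)
    expect_true(all(table(day[sp$calibration]) == 5))
  }
})

test_that("the CSV dialect round-trips and rejects malformed tables", {
  gen <- generate_dataset(tiny_config(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(gen$dataset, path)
  back <- read_spectra_csv(path)
  expect_equal(back$spectra, gen$dataset$spectra, tolerance = 1e-12)
  expect_equal(back$reference, gen$dataset$reference, tolerance = 1e-12)
  expect_identical(back$day, gen$dataset$day)
  expect_identical(back$sample_ids, gen$dataset$sample_ids)

  # missing reference column is allowed, not an error
  ds2 <- gen$dataset; ds2$reference <- NULL
  write_spectra_csv(ds2, path)
  expect_null(read_spectra_csv(path)$reference)

  writeLines(c("sample_id,700,650", "S1,0.5,0.6"), path)
  expect_error(read_spectra_csv(path), "increasing")
  writeLines(c("sample_id,650,700", "S1,0.5,abc"), path)
  expect_error(read_spectra_csv(path), "non-numeric")
})
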
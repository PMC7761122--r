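test_that("the retention schedule satisfies its boundary conditions", {
  expect_equal(edf_ratio(1, 50, 200), 1)
  expect_equal(edf_ratio(50, 50, 200), 2 / 200)
  expect_equal(edf_ratio(25, 50, 200), exp(-24 * log(100) / 49))
  expect_equal(edf_ratio(25, 50, 200), 0.105, tolerance = 1e-2)
  for (seed in 1:25) {
    np <- withr::with_seed(seed, c(sample(2:100, 1), sample(3:5000, 1)))
    expect_equal(edf_ratio(1, np[1], np[2]), 1)
    expect_equal(edf_ratio(np[1], np[1], np[2]), 2 / np[2])
    r <- edf_ratio(seq_len(np[1]), np[1], np[2])
    expect_true(all(diff(r) < 0))
  }
  expect_error(edf_ratio(1, 1, 100), "N")
  expect_error(edf_ratio(1, 10, 2), "p")
})

test_that("adaptive reweighted sampling respects weights", {
  expect_identical(adaptive_reweighted_sample(c(0, 1, 0), 1, seed = 1), 2L)
  expect_identical(adaptive_reweighted_sample(rep(1, 7), 7, seed = 1), 1:7)
  expect_warning(
    kept <- adaptive_reweighted_sample(c(0.5, 0, 0.5, 0), 3, seed = 1),
    "positive")
  expect_identical(kept, c(1L, 3L))

  draws <- vapply(seq_len(10000), function(i)
    adaptive_reweighted_sample(c(0.9, 0.05, 0.05), 1, seed = i), integer(1))
  expect_equal(mean(draws == 1L), 0.9, tolerance = 0.012)
})

test_that("CARS is seeded, capped by the schedule, and starts from all variables", {
  d <- planted_design(seed = 3, n = 60, n_informative = 5, n_noise = 45)
  cfg <- cars_config(n_iterations = 30, n_lv = 3, seed = 42)
  r1 <- run_cars(d$X, d$y, cfg)
  r2 <- run_cars(d$X, d$y, cfg)
  expect_identical(r1$selected_indices, r2$selected_indices)
  expect_identical(r1$rmsecv, r2$rmsecv)

  p <- ncol(d$X)
  counts <- lengths(r1$retained_sets)
  expect_identical(counts[1], p)
  caps <- pmax(2, round(edf_ratio(seq_len(30), 30, p) * p))
  expect_true(all(counts <= caps))
  expect_true(all(diff(counts) <= 0))
  # the winner attains the minimum scored RMSECV
  expect_equal(r1$rmsecv[r1$best_iteration], min(r1$rmsecv))
})

test_that("CARS recovers planted informative variables", {
  d <- planted_design(seed = 8, n = 80, n_informative = 5, n_noise = 55)
  res <- run_cars(d$X, d$y, cars_config(n_lv = 3, seed = 5))
  expect_gte(sum(res$selected_indices %in% d$informative), 4)
  expect_lte(res$rmsecv[res$best_iteration], res$rmsecv[1])
})
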
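# shared fixtures, all generated in code

# small wavelength grid covering the instrument range
tiny_grid <- function(step = 10) seq(650, 1100, by = step)

# random smooth-ish spectra for invariance checks
random_spectra <- function(n, wavelengths, seed = 1) {
  withr::with_seed(seed, {
    t(replicate(n, {
      0.2 + 0.8 * abs(stats::rnorm(1)) *
        exp(-0.5 * ((wavelengths - stats::runif(1, 700, 1050)) /
                      stats::runif(1, 20, 120))^2) +
        0.05 * stats::rnorm(length(wavelengths))
    }))
  })
}

# generator config scaled down for fast unit tests
tiny_config <- function(...) {
  synthetic_config(n_samples = 40L, wavelength_step = 10, n_days = 4L, ...)
}

# scatter-free configuration: identity multiplicative, no additive offset
identity_config <- function(..., noise_sd = 0) {
  synthetic_config(multiplicative_range = c(1, 1), additive_range = c(0, 0),
                   scatter_model = "EQ3", noise_sd = noise_sd, ...)
}

# planted CARS design: first 10 variables affine in y, the rest pure noise
planted_design <- function(seed, n = 100L, n_informative = 10L, n_noise = 190L) {
  withr::with_seed(seed, {
    y <- stats::runif(n, 31, 49)
    Xinf <- vapply(seq_len(n_informative), function(j) {
      stats::runif(1, -5, 5) +
        stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1) * y +
        stats::rnorm(n, sd = 0.5)
    }, numeric(n))
    Xnoise <- matrix(stats::rnorm(n * n_noise, sd = stats::sd(y)), n)
    list(X = cbind(Xinf, Xnoise), y = y, informative = seq_len(n_informative))
  })
}

# noise-free rank-3 regression system: y is exactly recoverable at 3 LVs
rank3_system <- function(seed, n = 100L, p = 10L) {
  withr::with_seed(seed, {
    scores <- matrix(stats::rnorm(n * 3), n)
    loadings <- matrix(stats::rnorm(p * 3), p)
    list(X = scores %*% t(loadings),
         y = drop(scores %*% c(1, -2, 0.5)) + 40)
  })
}
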
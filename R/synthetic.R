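#' Configuration for the synthetic spectra generator
#'
#' Describes the generative model behind the simulated VIS/NIR absorbance
#' spectra: Gaussian absorption bands on a 650-1100 nm grid, a juiciness
#' gradient over a multi-day storage experiment, per-sample multiplicative
#' scatter and additive baselines, and instrument noise. The ideal (chemical)
#' spectrum of sample i is
#' `x_chem_i = offset + w_bg * G_bg + sum_k w_k(J_i) * G_k`,
#' where the band weights of the informative bands are affine in the
#' juiciness `J_i`; the observed spectrum follows the selected scatter model:
#' `EQ3`: `x_i = a_i * x_chem_i + b_i`, or
#' `EQ4`: `x_i = a_i * x_chem_i + b_i + c_i * lambda + d_i * lambda^2`,
#' plus i.i.d. Gaussian noise.
#'
#' Defaults emulate the reference storage study: 127 pears over ten sampling
#' occasions, juiciness spanning 31.18-48.71 percent, absorption bands near
#' 675 (chlorophyll), 740 and 840 (water / carbohydrate) and 975 nm (water),
#' with the water-related bands carrying the juiciness signal.
#'
#' @param n_samples number of samples.
#' @param wavelength_start,wavelength_stop,wavelength_step grid in nm.
#' @param band_centers Gaussian band centers (nm).
#' @param band_widths Gaussian band standard deviations (nm).
#' @param band_weights band peak weights at mid-range juiciness (absorbance).
#' @param informative_band_indices which bands scale with juiciness.
#' @param juiciness_slopes per-band weight change per percent juiciness;
#'   zero outside `informative_band_indices`.
#' @param juiciness_range percent range covered by the samples.
#' @param juiciness_sampling `"uniform"` draws, or `"blocks"` for a
#'   rise-then-fall storage trend with day-level means.
#' @param n_days number of sampling occasions; samples fill days at up to
#'   `ceiling(n_samples / n_days)` per day, the last day taking the
#'   remainder (127 samples over 10 days gives 9 x 13 + 1 x 10).
#' @param background_center,background_width,background_weight broad
#'   background band (nm, nm, absorbance).
#' @param baseline_offset constant chemical offset (absorbance).
#' @param scatter_model `"EQ4"` (wavelength-dependent additive baseline,
#'   default) or `"EQ3"` (constant additive offset).
#' @param multiplicative_range interval for the per-sample path-length
#'   factor `a_i` (strictly positive).
#' @param additive_range interval for the constant offset `b_i`; under
#'   `EQ4` the lambda coefficients are drawn as
#'   `c_i ~ U(additive_range) / max(lambda)` and
#'   `d_i ~ U(additive_range) / max(lambda)^2`, so each additive term has
#'   magnitude comparable to `b_i` across the grid.
#' @param noise_sd instrument noise standard deviation (absorbance).
#' @param seed default seed used by [generate_dataset()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 127L,
                             wavelength_start = 650, wavelength_stop = 1100,
                             wavelength_step = 2,
                             band_centers = c(675, 740, 840, 975),
                             band_widths = c(12, 20, 25, 20),
                             band_weights = c(0.35, 0.45, 0.50, 0.80),
                             informative_band_indices = c(2L, 4L),
                             juiciness_slopes = NULL,
                             juiciness_range = c(31.18, 48.71),
                             juiciness_sampling = c("uniform", "blocks"),
                             n_days = 10L,
                             background_center = 900, background_width = 160,
                             background_weight = 0.45, baseline_offset = 0.15,
                             scatter_model = c("EQ4", "EQ3"),
                             multiplicative_range = c(0.7, 1.3),
                             additive_range = c(-0.2, 0.2),
                             noise_sd = 0.005,
                             seed = 1L) {
  juiciness_sampling <- match.arg(juiciness_sampling)
  scatter_model <- match.arg(scatter_model)
  k <- length(band_centers)
  if (length(band_widths) != k || length(band_weights) != k)
    stop("band_centers, band_widths and band_weights must have equal length")
  if (is.null(juiciness_slopes)) {
    juiciness_slopes <- numeric(k)
    juiciness_slopes[informative_band_indices] <-
      c(0.010, 0.018, 0.012, 0.008)[seq_along(informative_band_indices)]
  }
  if (length(juiciness_slopes) != k)
    stop("juiciness_slopes must have one entry per band")
  if (wavelength_step <= 0 || wavelength_stop <= wavelength_start)
    stop("wavelength grid must be strictly increasing")
  if (any(juiciness_range <= 0) || any(juiciness_range >= 100) ||
      juiciness_range[2] < juiciness_range[1])
    stop("juiciness_range must be an ordered pair within (0, 100)")
  if (any(multiplicative_range <= 0))
    stop("multiplicative coefficients must be strictly positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(n_samples = as.integer(n_samples),
         wavelengths = seq(wavelength_start, wavelength_stop, by = wavelength_step),
         band_centers = band_centers, band_widths = band_widths,
         band_weights = band_weights,
         informative_band_indices = as.integer(informative_band_indices),
         juiciness_slopes = juiciness_slopes,
         juiciness_range = juiciness_range,
         juiciness_sampling = juiciness_sampling,
         n_days = as.integer(n_days),
         background_center = background_center,
         background_width = background_width,
         background_weight = background_weight,
         baseline_offset = baseline_offset,
         scatter_model = scatter_model,
         multiplicative_range = multiplicative_range,
         additive_range = additive_range,
         noise_sd = noise_sd, seed = seed),
    class = "synthetic_config")
}

#' Per-sample scatter coefficients
#'
#' One `(a, b, c, d)` tuple per sample: `a` is the multiplicative
#' (path-length) factor, `b` the constant additive offset, and `c`, `d` the
#' coefficients on lambda and lambda squared of the wavelength-dependent
#' additive baseline (zero under the constant-offset model).
#'
#' @param a multiplicative coefficients (strictly positive).
#' @param b,c,d additive coefficients (per sample; `c`, `d` default to 0).
#' @return An object of class `scatter_params`.
#' @export
scatter_params <- function(a, b, c = 0, d = 0) {
  n <- length(a)
  b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(a <= 0)) stop("multiplicative coefficients a must be strictly positive")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "scatter_params")
}

# estimated (as opposed to generative) coefficients: fitted slopes may come
# out negative on pathological spectra, so positivity is not enforced here
estimated_scatter_params <- function(a, b, c = 0, d = 0) {
  n <- length(a)
  structure(list(a = as.numeric(a), b = rep_len(as.numeric(b), n),
                 c = rep_len(as.numeric(c), n), d = rep_len(as.numeric(d), n)),
            class = "scatter_params")
}

#' @export
print.scatter_params <- function(x, ...) {
  cat(sprintf("<scatter_params> %d samples; a in [%.3f, %.3f]; |c|,|d| %s\n",
              length(x$a), min(x$a), max(x$a),
              if (all(x$c == 0) && all(x$d == 0)) "zero (constant offset model)"
              else "non-zero (wavelength-dependent baseline)"))
  invisible(x)
}

#' Pure-component band spectra
#'
#' One unit-peak-height Gaussian per configured band, evaluated on the
#' wavelength grid. Because the grid is uniform, each component's maximum
#' falls on the grid point nearest its center.
#'
#' @param config a [synthetic_config()].
#' @return Matrix, bands in rows, wavelengths in columns.
#' @export
generate_component_bands <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wl <- config$wavelengths
  bad <- config$band_centers < min(wl) | config$band_centers > max(wl)
  if (any(bad))
    stop(sprintf("band center(s) outside the wavelength grid: %s nm",
                 paste(config$band_centers[bad], collapse = ", ")))
  t(vapply(seq_along(config$band_centers),
           function(k) exp(-0.5 * ((wl - config$band_centers[k]) /
                                     config$band_widths[k])^2),
           numeric(length(wl))))
}

#' Apply multiplicative and additive scatter effects
#'
#' Transforms ideal spectra into observed ones:
#' `row_i = a_i * ideal_i + b_i + c_i * lambda + d_i * lambda^2 + noise`.
#' Exposed separately from [generate_dataset()] so known effects can be
#' planted on arbitrary spectra.
#'
#' @param ideal matrix of ideal spectra (samples x wavelengths).
#' @param scatter a [scatter_params()] with one tuple per row of `ideal`.
#' @param wavelengths wavelength grid in nm (the raw grid, not rescaled).
#' @param noise_sd standard deviation of i.i.d. Gaussian noise.
#' @param seed seed for the noise draw.
#' @return Matrix of observed spectra.
#' @export
apply_scatter_effects <- function(ideal, scatter, wavelengths,
                                  noise_sd = 0, seed = NULL) {
  ideal <- as_spectra_matrix(ideal)
  stopifnot(inherits(scatter, "scatter_params"))
  wavelengths <- check_wavelengths(wavelengths, ncol(ideal))
  n <- nrow(ideal)
  if (length(scatter$a) != n) stop("one scatter tuple per sample is required")
  out <- ideal * scatter$a +
    outer(scatter$b, rep(1, length(wavelengths))) +
    outer(scatter$c, wavelengths) +
    outer(scatter$d, wavelengths^2)
  if (noise_sd > 0)
    out <- out + with_seed(seed, matrix(stats::rnorm(length(out), sd = noise_sd),
                                        nrow = n))
  dimnames(out) <- dimnames(ideal)
  out
}

#' Generate a synthetic juiciness-spectra dataset
#'
#' Draws juiciness values, builds the ideal (chemical) spectra whose
#' informative band weights are affine in juiciness, draws per-sample scatter
#' coefficients under the configured model, and returns both the observed
#' dataset and the full generating truth. Identical `config` and `seed`
#' reproduce the output bit for bit.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list with elements `dataset` (a [spectral_dataset()], absorbance
#'   mode, with `day` and `reference`) and `truth` (class `synthetic_truth`:
#'   `ideal_spectra`, `scatter`, `juiciness`,
#'   `informative_wavelength_indices`, `components`, `seed`).
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  wl <- config$wavelengths
  seeds <- derive_seeds(seed, 3L)

  per <- ceiling(n / config$n_days)
  sizes <- rep(per, config$n_days)
  sizes[config$n_days] <- sizes[config$n_days] - (sum(sizes) - n)
  if (sizes[config$n_days] <= 0) stop("n_days too large for n_samples")
  day <- rep(seq_len(config$n_days), times = sizes)

  jr <- config$juiciness_range
  juiciness <- with_seed(seeds[[1]], {
    if (config$juiciness_sampling == "uniform") {
      stats::runif(n, jr[1], jr[2])
    } else {
      # rise-then-fall storage trend: day means on an inverted parabola
      # peaking early in storage, plus within-day spread
      u <- (seq_len(config$n_days) - 1) / max(1, config$n_days - 1)
      trend <- 1 - ((u - 0.3) / 0.7)^2
      mid <- jr[1] + (0.25 + 0.55 * trend) * diff(jr)
      pmin(jr[2], pmax(jr[1], mid[day] + stats::rnorm(n, sd = 0.12 * diff(jr))))
    }
  })

  comps <- generate_component_bands(config)
  bg <- exp(-0.5 * ((wl - config$background_center) / config$background_width)^2)
  jmid <- mean(jr)
  # weights: rows = samples, cols = bands; informative bands affine in J
  W <- outer(juiciness - jmid, config$juiciness_slopes) +
    matrix(config$band_weights, n, length(config$band_weights), byrow = TRUE)
  ideal <- config$baseline_offset + config$background_weight *
    matrix(bg, n, length(wl), byrow = TRUE) + W %*% comps

  mr <- config$multiplicative_range
  ar <- config$additive_range
  scatter <- with_seed(seeds[[2]], {
    a <- stats::runif(n, mr[1], mr[2])
    b <- stats::runif(n, ar[1], ar[2])
    if (config$scatter_model == "EQ4") {
      lmax <- max(wl)
      scatter_params(a, b,
                     c = stats::runif(n, ar[1], ar[2]) / lmax,
                     d = stats::runif(n, ar[1], ar[2]) / lmax^2)
    } else {
      scatter_params(a, b)
    }
  })

  observed <- apply_scatter_effects(ideal, scatter, wl,
                                    noise_sd = config$noise_sd,
                                    seed = seeds[[3]])
  ds <- spectral_dataset(wl, observed, mode = "absorbance",
                         day = day, reference = juiciness)
  peak_idx <- vapply(config$informative_band_indices,
                     function(k) which.min(abs(wl - config$band_centers[k])),
                     integer(1))
  truth <- structure(
    list(ideal_spectra = ideal, scatter = scatter, juiciness = juiciness,
         informative_wavelength_indices = peak_idx,
         components = comps, seed = seed),
    class = "synthetic_truth")
  list(dataset = ds, truth = truth)
}

#' Write the generating truth of a synthetic dataset as JSON
#'
#' Sidecar to the spectra CSV: scatter coefficients, juiciness, informative
#' wavelength indices and the seed, so a simulated dataset can be audited
#' without rerunning the generator.
#'
#' @param truth a `synthetic_truth` from [generate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(
    list(scatter = truth$scatter[c("a", "b", "c", "d")],
         juiciness = truth$juiciness,
         informative_wavelength_indices = truth$informative_wavelength_indices,
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
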
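#' Replicated RAW-versus-LRC-SR benchmark
#'
#' Repeats the core comparison of the calibration study on freshly drawn
#' synthetic datasets: for each replicate a dataset is generated under the
#' default generative model (127 samples, wavelength-dependent additive
#' scatter, instrument noise), smoothed, split 100/27 by storage day, and
#' calibrated two ways — plain PLS on the raw smoothed spectra
#' (latent-variable count chosen by Monte Carlo cross-validation), and the
#' LRC-SR route: linear regression correction, spectral-ratio variables,
#' CARS selection, then PLS. Both models are scored on the external
#' validation set.
#'
#' @param n_replicates number of independent replicates.
#' @param seed master seed; each replicate derives its own streams.
#' @param config a [synthetic_config()] describing the data-generating
#'   conditions.
#' @param mccv_reps Monte Carlo cross-validation repetitions per model.
#' @param lv_range candidate latent-variable counts.
#' @param cars_iterations CARS iterations.
#' @return A data frame with one row per replicate: `raw_r2v`, `raw_rmsev`,
#'   `lrcsr_r2v`, `lrcsr_rmsev`, `lrcsr_n_selected`,
#'   `raw_max_abs_corr`, `lrcsr_best_abs_corr`.
#' @export
run_benchmark <- function(n_replicates = 25L, seed = 1L,
                          config = synthetic_config(),
                          mccv_reps = 20L, lv_range = 1:15,
                          cars_iterations = 50L) {
  rep_seeds <- derive_seeds(seed, n_replicates)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seeds <- derive_seeds(rep_seeds[[r]], 6L)
    gen <- generate_dataset(config, seed = seeds[[1]])
    ds <- gen$dataset
    sm <- sg_smooth(ds$spectra)
    split <- split_calibration_validation(ds, per_day = 10L, seed = seeds[[2]])
    cal <- split$calibration; val <- split$validation
    ycal <- ds$reference[cal]; yval <- ds$reference[val]
    Xcal <- sm[cal, , drop = FALSE]; Xval <- sm[val, , drop = FALSE]

    # RAW route: PLS on all wavelengths
    cv_raw <- mccv(Xcal, ycal, lv_range = lv_range, n_reps = mccv_reps,
                   seed = seeds[[3]])
    raw_model <- fit_pls(Xcal, ycal, cv_raw$chosen_lv)
    raw_val <- external_validate(raw_model, Xval, yval)

    # LRC-SR route: additive correction, ratio variables, CARS, PLS
    lrc <- lrc_correct(Xcal)
    rat_cal <- build_spectral_ratios(lrc$corrected, ds$wavelengths)
    rat_val <- build_spectral_ratios(
      lrc_correct(Xval, reference = lrc$reference_spectrum)$corrected,
      ds$wavelengths, pairs = rat_cal$pair_indices)
    cv_sr <- mccv(rat_cal$values, ycal, lv_range = lv_range,
                  n_reps = mccv_reps, seed = seeds[[4]])
    cars <- run_cars(rat_cal$values, ycal,
                     cars_config(n_iterations = cars_iterations,
                                 n_lv = cv_sr$chosen_lv, seed = seeds[[5]]))
    sel <- cars$selected_indices
    cv_sel <- mccv(rat_cal$values[, sel, drop = FALSE], ycal,
                   lv_range = lv_range[lv_range <= length(sel)],
                   n_reps = mccv_reps, seed = seeds[[6]])
    sr_model <- fit_pls(rat_cal$values[, sel, drop = FALSE], ycal,
                        cv_sel$chosen_lv)
    sr_val <- external_validate(sr_model, rat_val$values[, sel, drop = FALSE],
                                yval)

    rows[[r]] <- data.frame(
      replicate = r,
      raw_r2v = raw_val$r2v, raw_rmsev = raw_val$rmsev,
      lrcsr_r2v = sr_val$r2v, lrcsr_rmsev = sr_val$rmsev,
      lrcsr_n_selected = length(sel),
      raw_max_abs_corr = max(abs(univariate_correlation(Xcal, ycal)),
                             na.rm = TRUE),
      lrcsr_best_abs_corr = max(abs(univariate_correlation(rat_cal$values,
                                                           ycal)),
                                na.rm = TRUE))
  }
  do.call(rbind, rows)
}
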
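#' Pipeline configuration
#'
#' Bundles every stage setting of the end-to-end workflow: data source
#' (synthetic generator or CSV), smoothing, the preprocessing method list,
#' the day-stratified split, Monte Carlo cross-validation, CARS, and the
#' master seed from which every stochastic stage derives its own stream.
#'
#' @param synthetic a [synthetic_config()]; ignored when `input_csv` is set.
#' @param input_csv optional path to a spectra CSV (absorbance mode) with
#'   `day` and `juiciness` columns.
#' @param methods preprocessing methods to compare, from `"raw"`, `"nor"`,
#'   `"fd"`, `"det"`, `"snv"`, `"msc"`, `"pqn"`, `"oplecm"`, `"ops_sr"`,
#'   `"lrc_sr"`.
#' @param per_day calibration samples drawn per storage day.
#' @param sg_window,sg_polyorder Savitzky-Golay smoothing parameters.
#' @param lv_range candidate latent-variable counts.
#' @param mccv_reps,mccv_fraction Monte Carlo cross-validation protocol.
#' @param cars_iterations,cars_fraction,cars_folds CARS protocol.
#' @param denominator_floor spectral-ratio denominator floor
#'   (`NULL` = data-driven default, see [build_spectral_ratios()]).
#' @param seed master seed.
#' @param out_dir optional directory for on-disk artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), input_csv = NULL,
                            methods = c("raw", "nor", "fd", "det", "snv", "msc",
                                        "pqn", "oplecm", "ops_sr", "lrc_sr"),
                            per_day = 10L, sg_window = 9L, sg_polyorder = 2L,
                            lv_range = 1:20, mccv_reps = 100L,
                            mccv_fraction = 0.8,
                            cars_iterations = 50L, cars_fraction = 0.8,
                            cars_folds = 5L,
                            denominator_floor = NULL,
                            seed = 1L, out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(synthetic = synthetic, input_csv = input_csv,
                 methods = methods, per_day = as.integer(per_day),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 lv_range = as.integer(lv_range),
                 mccv_reps = as.integer(mccv_reps),
                 mccv_fraction = mccv_fraction,
                 cars_iterations = as.integer(cars_iterations),
                 cars_fraction = cars_fraction,
                 cars_folds = as.integer(cars_folds),
                 denominator_floor = denominator_floor,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

method_label <- function(method) {
  c(raw = "RAW", nor = "NOR", fd = "FD", det = "DET", snv = "SNV",
    msc = "MSC", pqn = "PQN", oplecm = "OPLECm", ops_sr = "OPS-SR",
    lrc_sr = "LRC-SR")[[method]]
}

# fit the preprocessing on calibration spectra and apply it (with frozen
# reference where the method has one) to the validation spectra; for the
# *-SR methods the returned variables are the ratio variables
prep_variables <- function(method, Xcal, Xval, wl, floor = NULL) {
  sr <- function(corr_cal, corr_val) {
    rat_cal <- build_spectral_ratios(corr_cal, wl, denominator_floor = floor)
    rat_val <- build_spectral_ratios(corr_val, wl, pairs = rat_cal$pair_indices)
    list(cal = rat_cal$values, val = rat_val$values, ratios = rat_cal)
  }
  switch(method,
    raw = list(cal = Xcal, val = Xval),
    nor = list(cal = normalize_nor(Xcal)$corrected,
               val = normalize_nor(Xval)$corrected),
    fd = list(cal = first_derivative(Xcal, wl)$corrected,
              val = first_derivative(Xval, wl)$corrected),
    det = list(cal = detrend(Xcal, wl)$corrected,
               val = detrend(Xval, wl)$corrected),
    snv = list(cal = snv(Xcal)$corrected, val = snv(Xval)$corrected),
    msc = {
      res <- msc(Xcal)
      list(cal = res$corrected,
           val = msc(Xval, reference = res$reference_spectrum)$corrected)
    },
    pqn = {
      res <- pqn(Xcal)
      list(cal = res$corrected,
           val = pqn(Xval, reference = res$reference_spectrum)$corrected)
    },
    oplecm = list(cal = Xcal, val = Xval),
    ops_sr = sr(ops_project(Xcal, wl)$corrected,
                ops_project(Xval, wl)$corrected),
    lrc_sr = {
      res <- lrc_correct(Xcal)
      sr(res$corrected,
         lrc_correct(Xval, reference = res$reference_spectrum)$corrected)
    },
    stop(sprintf("unknown preprocessing method '%s'", method)))
}

run_method <- function(method, vars, wl, ycal, yval, cal_ids, val_ids,
                       config, seeds) {
  Vcal <- vars$cal; Vval <- vars$val
  is_oplecm <- method == "oplecm"
  fit_fun <- if (is_oplecm) {
    function(X, y, n_lv) oplecm_correct(X, y, n_lv, wl)
  } else fit_pls
  ppath <- if (is_oplecm) oplecm_predict_path else pls_predict_path

  feasible <- function(V) min(floor(config$mccv_fraction * nrow(V)) - 1L, ncol(V))
  lv1 <- config$lv_range[config$lv_range <= feasible(Vcal)]
  cv_full <- mccv(Vcal, ycal, lv_range = lv1, n_reps = config$mccv_reps,
                  split_fraction = config$mccv_fraction, seed = seeds[[1]],
                  fit_fun = fit_fun, predict_path_fun = ppath)

  cars <- run_cars(Vcal, ycal,
                   cars_config(n_iterations = config$cars_iterations,
                               mc_sample_fraction = config$cars_fraction,
                               n_lv = cv_full$chosen_lv,
                               cv_folds = config$cars_folds,
                               seed = seeds[[2]]))
  sel <- cars$selected_indices

  fit_fun_sel <- if (is_oplecm) {
    function(X, y, n_lv) oplecm_correct(X, y, n_lv, wl[sel])
  } else fit_pls
  lv2 <- config$lv_range[config$lv_range <= min(feasible(Vcal), length(sel))]
  cv_sel <- mccv(Vcal[, sel, drop = FALSE], ycal, lv_range = lv2,
                 n_reps = config$mccv_reps,
                 split_fraction = config$mccv_fraction, seed = seeds[[3]],
                 fit_fun = fit_fun_sel, predict_path_fun = ppath)

  model <- fit_fun_sel(Vcal[, sel, drop = FALSE], ycal, cv_sel$chosen_lv)
  validation <- external_validate(model, Vval[, sel, drop = FALSE], yval,
                                  calibration_ids = cal_ids,
                                  validation_ids = val_ids)
  i <- match(cv_sel$chosen_lv, cv_sel$table$lv)
  list(cv_full = cv_full, cars = cars, cv_subset = cv_sel, model = model,
       validation = validation, ratios = vars$ratios,
       max_abs_corr = max(abs(univariate_correlation(Vcal, ycal)), na.rm = TRUE),
       row = data.frame(
         method = method_label(method),
         n_lv = cv_sel$chosen_lv,
         n_selected = length(sel),
         r2cv = cv_sel$table$r2cv[i],
         rmsecv = cv_sel$table$rmsecv[i],
         r2v = validation$r2v,
         rmsev = validation$rmsev,
         max_relative_error = validation$max_relative_error,
         mean_relative_error = validation$mean_relative_error,
         stringsAsFactors = FALSE))
}

#' Run the full method-comparison pipeline
#'
#' Executes, for every configured preprocessing method: data loading or
#' synthesis, Savitzky-Golay smoothing, the day-stratified
#' calibration/validation split, preprocessing (reference spectra fitted on
#' the calibration set and frozen for validation; the spectral-ratio step
#' applied after LRC and OPS only), Monte Carlo cross-validation for
#' latent-variable selection, CARS variable selection, cross-validation of
#' the selected subset, and external validation. Rerunning with the same
#' configuration and seed reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result`: the comparison `report`
#'   (one row per method: latent variables, selected-variable count, R2cv,
#'   RMSEcv, R2v, RMSEv, max/mean relative error), per-method detail
#'   objects, the dataset, split and (for synthetic input) generating
#'   truth. Artifacts are written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  n_methods <- length(config$methods)
  seeds <- derive_seeds(config$seed, 2L + 3L * n_methods)

  if (!is.null(config$input_csv)) {
    dataset <- read_spectra_csv(config$input_csv)
    truth <- NULL
    if (is.null(dataset$reference)) stop("input CSV has no juiciness column")
    if (is.null(dataset$day)) stop("input CSV has no day column")
  } else {
    gen <- generate_dataset(config$synthetic, seed = seeds[[1]])
    dataset <- gen$dataset
    truth <- gen$truth
  }

  smoothed <- sg_smooth(dataset$spectra, config$sg_window, config$sg_polyorder)
  split <- split_calibration_validation(dataset, per_day = config$per_day,
                                        seed = seeds[[2]])
  wl <- dataset$wavelengths
  cal <- split$calibration; val <- split$validation
  Xcal <- smoothed[cal, , drop = FALSE]
  Xval <- smoothed[val, , drop = FALSE]
  ycal <- dataset$reference[cal]
  yval <- dataset$reference[val]

  methods <- vector("list", n_methods)
  names(methods) <- config$methods
  rows <- vector("list", n_methods)
  for (m in seq_len(n_methods)) {
    method <- config$methods[m]
    vars <- prep_variables(method, Xcal, Xval, wl,
                           floor = config$denominator_floor)
    res <- run_method(method, vars, wl, ycal, yval,
                      dataset$sample_ids[cal], dataset$sample_ids[val],
                      config, seeds[2L + 3L * (m - 1L) + 1:3])
    methods[[m]] <- res
    rows[[m]] <- cbind(res$row, max_abs_corr = res$max_abs_corr)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  result <- structure(list(report = report, methods = methods,
                           dataset = dataset, truth = truth, split = split,
                           smoothed = smoothed, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(cbind(x$report[, 1:3],
              round(x$report[, -(1:3)], 3)), row.names = FALSE)
  invisible(x)
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$report, file.path(dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_spectra_csv(result$dataset, file.path(dir, "dataset.csv"))
  if (!is.null(result$truth))
    write_truth_json(result$truth, file.path(dir, "truth.json"))
  jsonlite::write_json(
    list(calibration = result$split$calibration,
         validation = result$split$validation,
         per_day = result$split$per_day, seed = result$split$seed),
    file.path(dir, "split.json"), auto_unbox = TRUE)
  sel <- lapply(result$methods, function(m) m$cars$selected_indices)
  jsonlite::write_json(sel, file.path(dir, "selected_variables.json"))
  invisible(dir)
}

#' Render the pipeline's diagnostic figures
#'
#' Writes up to four PNG files into `dir`: the smoothed spectra, the
#' ratio-correlation heat map (first *-SR method present), the
#' RMSEcv-versus-LV curves, and the predicted-versus-measured scatter of
#' the best validated method. Figures whose inputs are missing are skipped
#' with a warning.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return Character vector of the files written, invisibly.
#' @export
pipeline_figures <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  png_dev <- function(name) {
    path <- file.path(dir, name)
    grDevices::png(path, width = 900, height = 650, res = 110)
    path
  }

  files <- c(files, png_dev("spectra.png"))
  graphics::matplot(result$dataset$wavelengths, t(result$smoothed),
                    type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    xlab = "Wavelength (nm)", ylab = "Absorbance (a.u.)")
  grDevices::dev.off()

  sr <- Filter(function(m) !is.null(m$ratios), result$methods)
  if (length(sr)) {
    cal <- result$split$calibration
    cmap <- ratio_correlation_map(sr[[1]]$ratios,
                                  result$dataset$reference[cal])
    files <- c(files, png_dev("correlation_map.png"))
    plot(cmap)
    grDevices::dev.off()
  } else {
    warning("no spectral-ratio method in the run; skipping correlation map")
  }

  files <- c(files, png_dev("rmsecv_curves.png"))
  tabs <- lapply(result$methods, function(m) m$cv_full$table)
  graphics::plot(NA, xlim = range(unlist(lapply(tabs, `[[`, "lv"))),
                 ylim = range(unlist(lapply(tabs, `[[`, "rmsecv"))),
                 xlab = "Latent variables", ylab = "RMSEcv (%)")
  for (i in seq_along(tabs))
    graphics::lines(tabs[[i]]$lv, tabs[[i]]$rmsecv, col = i, type = "b",
                    pch = 16, cex = 0.6)
  graphics::legend("topright", legend = result$report$method, col =
                     seq_along(tabs), lty = 1, cex = 0.7, bty = "n")
  grDevices::dev.off()

  best <- which.max(result$report$r2v)
  files <- c(files, png_dev("predicted_vs_measured.png"))
  plot(result$methods[[best]]$validation,
       main = result$report$method[best])
  grDevices::dev.off()

  invisible(files)
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Scalar fields map one-to-one onto [pipeline_config()] arguments; a
#' `synthetic:` block maps onto [synthetic_config()].
#'
#' @param path YAML (needs the `yaml` package) or JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  syn <- do.call(synthetic_config, raw$synthetic %||% list())
  raw$synthetic <- NULL
  do.call(pipeline_config, c(list(synthetic = syn), raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
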
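#' External validation of a calibration model
#'
#' Predicts an independent validation set and reports the external
#' determination coefficient `R2v`, root mean square error `RMSEv`, and the
#' maximum and mean relative prediction error
#' (`|y_hat - y| / y * 100`, percent). Per-sample predictions and relative
#' deviations are retained for plotting.
#'
#' @param model a fitted model with a `predict` method ([fit_pls()] or
#'   [oplecm_correct()]).
#' @param X_val validation variable matrix.
#' @param y_val validation reference values (must be strictly positive, or
#'   relative errors are undefined).
#' @param calibration_ids,validation_ids optional sample id vectors; when
#'   both are given they must be disjoint.
#' @return An object of class `validation_report` with fields `r2v`,
#'   `rmsev`, `max_relative_error`, `mean_relative_error` and a per-sample
#'   `predictions` data frame.
#' @export
external_validate <- function(model, X_val, y_val,
                              calibration_ids = NULL, validation_ids = NULL) {
  y_val <- as.numeric(y_val)
  if (any(y_val <= 0))
    stop("relative error undefined: validation reference values must be > 0")
  if (!is.null(calibration_ids) && !is.null(validation_ids) &&
      length(intersect(calibration_ids, validation_ids)))
    stop("calibration and validation sets overlap")
  y_hat <- as.numeric(predict(model, X_val))
  rel <- abs(y_hat - y_val) / y_val * 100
  structure(list(
    r2v = r2_metric(y_hat, y_val),
    rmsev = rmse_metric(y_hat, y_val),
    max_relative_error = max(rel),
    mean_relative_error = mean(rel),
    predictions = data.frame(
      sample_id = if (is.null(validation_ids)) seq_along(y_val) else validation_ids,
      measured = y_val, predicted = y_hat,
      deviation = y_hat - y_val, relative_error = rel)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d: R2v = %.3f, RMSEv = %.3f%%\n",
              nrow(x$predictions), x$r2v, x$rmsev))
  cat(sprintf("  relative error: max %.2f%%, mean %.2f%%\n",
              x$max_relative_error, x$mean_relative_error))
  invisible(x)
}

#' Predicted-versus-measured scatter plot
#'
#' Points are colored by relative deviation; the identity line marks
#' perfect prediction.
#'
#' @param x a [external_validate()] report.
#' @param ... passed to [graphics::plot()].
#' @export
plot.validation_report <- function(x, ...) {
  d <- x$predictions
  pal <- grDevices::hcl.colors(100, "Blue-Red 2")
  col <- pal[pmin(100L, pmax(1L, findInterval(
    d$relative_error, seq(0, max(d$relative_error) + 1e-9, length.out = 101))))]
  graphics::plot(d$measured, d$predicted, pch = 16, col = col,
                 xlab = "Measured juiciness (%)",
                 ylab = "Predicted juiciness (%)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("R2v = %.3f, RMSEv = %.2f%%", x$r2v, x$rmsev))
  invisible(x)
}
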
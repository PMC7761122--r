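#' Univariate wavelength-response correlations
#'
#' Pearson correlation of every column of a variable matrix with the
#' response. Constant columns yield `NA` (flagged, not an error); a constant
#' response is an error.
#'
#' @param X variable matrix, at least 3 rows.
#' @param y response vector.
#' @return Numeric vector of correlations, one per column.
#' @export
univariate_correlation <- function(X, y) {
  X <- as_spectra_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 3L) stop("need at least 3 samples")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (stats::sd(y) == 0) stop("response y is constant")
  suppressWarnings(as.numeric(stats::cor(X, y)))
}

#' Correlation map over spectral-ratio variables
#'
#' Correlates every retained ratio variable with the response and arranges
#' the absolute correlations on a (numerator wavelength) x (denominator
#' wavelength) square; the diagonal and floor-dropped pairs are `NA`. Both
#' orientations `(j, k)` and `(k, j)` are present and independently
#' computed. The headline value is the signed correlation of the arg-max
#' pair.
#'
#' @param ratios a [build_spectral_ratios()] result.
#' @param y response vector.
#' @return An object of class `correlation_map`: `axis_wavelengths`,
#'   `values` (matrix of `|r|`), `best_pair` (numerator, denominator nm),
#'   `best_pair_indices`, and signed `best_r`.
#' @export
ratio_correlation_map <- function(ratios, y) {
  stopifnot(inherits(ratios, "ratio_variable_set"))
  r <- univariate_correlation(ratios$values, y)
  wl <- ratios$source_wavelengths
  p <- length(wl)
  values <- matrix(NA_real_, p, p,
                   dimnames = list(format(wl, trim = TRUE),
                                   format(wl, trim = TRUE)))
  values[ratios$pair_indices] <- abs(r)
  best <- which.max(abs(r))
  structure(list(axis_wavelengths = wl, values = values,
                 best_pair = wl[ratios$pair_indices[best, ]],
                 best_pair_indices = ratios$pair_indices[best, ],
                 best_r = r[best]),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d x %d wavelengths; best |r| = %.3f (signed %.3f) at %g / %g nm\n",
              length(x$axis_wavelengths), length(x$axis_wavelengths),
              abs(x$best_r), x$best_r, x$best_pair[1], x$best_pair[2]))
  invisible(x)
}

#' Heat map of absolute ratio-response correlations
#'
#' Color encodes `|r|` (unsigned, like the usual published maps); the
#' signed headline value is available as `x$best_r`.
#'
#' @param x a [ratio_correlation_map()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.correlation_map <- function(x, ...) {
  graphics::image(x$axis_wavelengths, x$axis_wavelengths, x$values,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "Numerator wavelength (nm)",
                  ylab = "Denominator wavelength (nm)",
                  zlim = c(0, 1), ...)
  graphics::points(x$best_pair[1], x$best_pair[2], pch = 4, cex = 1.2)
  invisible(x)
}
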
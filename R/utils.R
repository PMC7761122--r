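# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs code on the current
# stream (still advancing it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministically derive `n` sub-seeds (< 2^31) from a master seed, so each
# pipeline stage gets an independent, reproducible stream.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max, n)))
}

as_spectra_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("spectra matrix contains missing values")
  x
}

check_wavelengths <- function(wavelengths, p = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (anyNA(wavelengths)) stop("wavelengths contain missing values")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!is.null(p) && length(wavelengths) != p)
    stop(sprintf("expected %d wavelengths, got %d", p, length(wavelengths)))
  wavelengths
}

# Map wavelengths to [-1, 1] before building {1, u, u^2}: a pure
# reparameterization of the same span, kept for numerical conditioning.
scaled_lambda <- function(wavelengths) {
  r <- range(wavelengths)
  if (diff(r) == 0) return(rep(0, length(wavelengths)))
  2 * (wavelengths - r[1]) / diff(r) - 1
}

# Orthonormal basis of span{1, u, ..., u^degree} on the scaled grid.
baseline_basis <- function(wavelengths, degree = 2L) {
  u <- scaled_lambda(wavelengths)
  B <- vapply(0:degree, function(k) u^k, numeric(length(u)))
  qr.Q(qr(B))
}
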
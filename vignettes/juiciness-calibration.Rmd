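---
title: "Scatter-corrected VIS/NIR calibration of fruit juiciness: methods and design"
author: "juicenir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scatter-corrected VIS/NIR calibration of fruit juiciness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Juiciness — the percent mass of juice a fruit's flesh releases under
compression — is a destructive reference measurement: the fruit cannot be
sold afterwards. Visible/near-infrared (VIS/NIR) spectroscopy over
650–1100 nm probes the O–H and C–H overtone bands of the constituents that
drive juiciness (water, starch, pectin), so a multivariate calibration of
juiciness against spectra makes non-destructive grading possible. The
obstacle is light scattering: sample-to-sample differences in particle size
and optical path length superimpose, on every spectrum, a multiplicative
distortion and an additive baseline that together dwarf the chemical signal.

`juicenir` implements the full comparison workflow for this problem: nine
scatter-correction preprocessing methods, spectral-ratio variable
construction, competitive adaptive reweighted sampling (CARS) for variable
selection, and single-response partial least squares (PLS) regression
evaluated by Monte Carlo cross-validation (MCCV) and external validation —
together with a synthetic spectra generator that reproduces the statistical
structure the methods assume, so that every stage is testable without
instrument data.

## The scatter models

Two generative assumptions organize the preprocessing methods. Writing
$x_i$ for the observed absorbance spectrum of sample $i$ and $x_{i,chem}$
for its ideal (chemical) spectrum, the constant-offset model is

$$x_i = a_i\, x_{i,chem} + b_i \mathbf{1},$$

with a per-sample multiplicative (path-length) factor $a_i > 0$ and a
constant additive offset $b_i$. The wavelength-dependent model adds a
polynomial baseline in the wavelength $\lambda$:

$$x_i = a_i\, x_{i,chem} + b_i \mathbf{1} + c_i \lambda + d_i \lambda^2.$$

NOR, SNV, MSC, PQN and LRC target the first model; DET, OPS and OPLECm the
second. LRC and OPS are deliberately *additive-only* corrections: they
leave $a_i$ in place, and the subsequent spectral-ratio step — every
ordered pair of wavelength columns divided elementwise — cancels it
exactly, since $(a_i s_j)/(a_i s_k) = s_j/s_k$. That exact cancellation,
verified to 1e-8 in the test suite, is the core trick of the LRC-SR and
OPS-SR routes.

## Pipeline stages and their parameters

- **Savitzky–Golay smoothing** (`sg_smooth()`): second-order polynomial,
  9-point window, applied before any correction. These are the reference
  protocol's values; the window is in grid points (2 nm spacing by
  default). The first derivative (`first_derivative()`) reuses the same
  filter with `m = 1`, scaled to absorbance per nm, rather than a separate
  finite difference — one pass, no double-smoothing edge artifacts.
- **NOR** is defined here as unit-Euclidean-norm row scaling (an area-norm
  option exists); the field uses "normalization" loosely and this is the
  most common reading.
- **MSC / LRC / PQN reference spectra** are estimated on the calibration
  set only and frozen before validation spectra are corrected — the
  validation set must not inform any fitted quantity.
- **DET / OPS / OPLECm baseline basis**: $\{1, \lambda, \lambda^2\}$ with
  $\lambda$ rescaled to $[-1, 1]$ before orthonormalization. This is a pure
  reparameterization of the same span, kept for numerical conditioning.
- **Spectral ratios** (`build_spectral_ratios()`): all ordered pairs
  $(j, k)$, $j \neq k$, in lexicographic order, matching full-square
  correlation maps. Pairs whose denominator magnitude falls below
  `denominator_floor` for any calibration sample are dropped. The default
  floor is **2% of the largest absolute corrected value**. This is
  deliberately aggressive: OPS output is orthogonal to the baseline span
  and therefore crosses zero on every spectrum, and a ratio against a
  near-zero denominator is a noise amplifier whose scale is orders of
  magnitude above every informative variable. PLS is scale-sensitive, and
  a handful of such columns is enough to destroy the calibration; with a
  permissive floor (say 1e-6 of the maximum) the OPS-SR route fails
  outright, while any floor of a few percent restores it. The floor is a
  parameter, and dropped pairs are counted in the returned object.
- **CARS** (`run_cars()`): N = 50 iterations, 80% row subsampling, 5-fold
  subset scoring — the hyperparameters of the originating CARS literature,
  since the application protocol leaves them unstated; all are exposed in
  `cars_config()`. The retention schedule is the exponentially decreasing
  function $r_i = a e^{-k i}$ with $r_1 = 1$ and $r_N = 2/p$ pinned, and
  survivors are drawn by weighted sampling *without* replacement with
  probability proportional to the absolute PLS coefficients. Subsets are
  scored on folds fixed across iterations, so the trajectory is comparable
  and the winner (minimum RMSECV; ties to fewer variables, then the
  earlier iteration) can be checked against the full-variable model on the
  same folds.
- **PLS** (`fit_pls()`): mean-centered single-response PLS with sequential
  deflation (NIPALS-equivalent scores/weights/loadings), implemented with
  a kernel recurrence that deflates only the covariance vector $X'y$, so
  the (possibly 50,000-column) ratio matrix is never copied per component.
  The full coefficient path is exposed: one fit at the largest component
  count yields predictions for every smaller count, which is what makes
  MCCV over 1–20 latent variables affordable.
- **MCCV** (`mccv()`): 100 random 80/20 calibration/hold-out splits by
  default. Squared errors are pooled over repetitions and divided by the
  total number of predictions; the literal reading of the printed formula
  (divide by repetitions × full sample count) is available as
  `pooling = "as_printed"`, and understates the error by a known constant
  factor since only the hold-out fraction is predicted per repetition.
- **Determination coefficient**: the printed cross-validation formula puts
  $\sum(\hat y_i - y_m)^2$ in the denominator, which yields 0 for shrunk
  but perfectly correlated predictions; `r2_metric()` defaults to the
  standard $\sum(y_i - y_m)^2$ denominator and exposes the as-printed
  variant. The ambiguity is preserved, not silently resolved.
- **Juiciness reference** (`compute_juiciness()`): implemented exactly as
  printed, $J = (W_2 - W_1)/W_1 \times 100$, although that is negative
  whenever compression loses mass while reported juiciness values are
  positive; a documented `sign_convention = "mass_loss"` switch covers
  rigs where $W_2$ is the post-compression pulp weight.

## OPLECm: the dual-model route

OPLECm never divides the spectrum by an estimated factor; it handles the
multiplicative effect in the regression instead. The estimator here works
as follows. Under the wavelength-dependent model, after projecting out
$\{1, \lambda, \lambda^2\}$, each calibration spectrum lies (up to noise)
in a two-dimensional subspace with coordinates proportional to
$(p_i,\; p_i y_i)$, where $p_i$ is the path-length factor and $y_i$ the
known calibration reference value. A rank-2 SVD recovers the subspace; a
homogeneous least-squares problem then finds the in-plane direction whose
coordinate ratio reproduces the $y_i$, giving $\hat p$ up to scale, which
is fixed by normalizing to unit mean. Two PLS models are trained — one on
$p_i y_i$, one on $p_i$ — and a new sample is predicted as the ratio of
the two model outputs, cancelling its unknown factor. Degenerate inputs
are handled explicitly: if $\hat p$ is numerically constant
(scatter-free data) the second model is the constant 1 and the route
reduces exactly to plain PLS; predicted factors below tolerance raise an
error outside cross-validation and are clamped inside it, where a
blown-up ratio should score badly rather than abort the protocol.

## What the generator emulates — and what it does not

`synthetic_config()` defaults describe the study conditions end to end:
127 samples over ten storage occasions (13 per day, the last day taking
the remainder), juiciness uniform on 31.18–48.71%, Gaussian absorption
bands at 675, 740, 840 and 975 nm over a broad background, the water
bands (740, 975 nm) carrying the juiciness signal with affine weights,
per-sample scatter $a_i \sim U(0.7, 1.3)$, $b_i \sim U(-0.2, 0.2)$, and
$c_i, d_i$ scaled so each additive term is comparable to $b_i$ across the
grid, plus i.i.d. Gaussian absorbance noise (sd 0.005). Under these
conditions the raw spectra's best univariate correlation with juiciness
sits around 0.2–0.5 — the degradation regime the preprocessing methods
exist for.

Two features of real data are deliberately absent. First, there is no
interfering constituent whose concentration varies independently across
samples and overlaps the informative bands: the ideal spectra are exactly
affine in juiciness, which is what makes exact-recovery properties
testable (the generator contract pins the correlation at an informative
peak to 1.0 absent scatter and noise). The consequence is that any method
which fully removes its scatter model leaves nearly perfect variables, so
corrected-spectrum correlations and validation R² on synthetic data are
optimistic relative to instrument data, and differences between the
well-matched methods (SNV vs MSC vs LRC-SR) are compressed. Passing tests
therefore demonstrate that each method removes exactly the distortion it
claims to remove — not that the field-observed ranking of close
competitors would reproduce. Second, noise is i.i.d. in absorbance;
wavelength-correlated instrument drift is not simulated. The
raw-versus-LRC-SR ordering, by contrast, is driven by the multiplicative
interaction $a_i y_i$ that no linear model on raw spectra can remove, and
is a robust property of these conditions: the replicated benchmark
(`run_benchmark()`) verifies it across independently generated datasets.

## Numerical choices

- Latent-variable selection resolves near-ties (relative RMSEcv difference
  below 1e-8) toward fewer components. On noise-free rank-deficient
  systems every sufficient count attains zero error up to float noise, and
  the parsimony rule selects the true dimension; on real data differences
  this small never arise.
- PLS component extraction stops when the response covariance is exhausted
  (norm below 1e-14 relative); later requested components repeat the last
  informative one, so the coefficient path stays well-defined.
- MSC errors on fitted slopes below 1e-10 (the correction divides by
  them). Estimated slopes are not forced positive: on pathological spectra
  a negative slope is a legitimate fit result, unlike the generative
  parameters where $a_i > 0$ is enforced.
- The day-stratified splitter is parameterized by the per-day calibration
  count rather than hard-coding 100/27, since 13 samples/day over 10
  occasions is arithmetically inconsistent with 127 samples; the default
  filling (9 × 13 + 1 × 10) reproduces the 100/27 protocol.
- All stochastic stages (generator, splits, MCCV, CARS subsampling and
  survivor draws) derive independent sub-seeds from one master seed;
  reruns are bit-identical, and the caller's RNG state is restored.

## Problem sizes used by the shipped checks

The test suite exercises identities on 100 random spectra at 1e-8,
recovery of planted scatter coefficients to 1e-6 on noise-free batches,
CARS retrieval of 10 planted informative variables among 190 noise
variables (20 seeds, n = 100), the PLS/OLS equivalence on 50 random
full-rank problems, and a 25-replicate raw-versus-LRC-SR benchmark at the
default conditions with 20 MCCV repetitions per model and latent variables
1–15 — sizes chosen so the whole suite completes in minutes while leaving
each property's verdict unambiguous. `scripts/acceptance.R` runs the full
ten-method comparison at the default protocol (100 MCCV repetitions,
latent variables 1–20, 50 CARS iterations) on one generated dataset.

## Known limitations

- The generator's rank-2 chemical structure (fixed background + affine
  juiciness signal) matches the OPLECm estimator's model class; spectra
  with several independently varying constituents would require the
  estimator's subspace dimension to grow, which is not implemented.
- Relative errors are undefined for non-positive reference values, so the
  validation report refuses them; juiciness is strictly positive in
  practice.
- No second-derivative, EMSC, wavelet or orthogonal-signal corrections,
  and no transfer between fruit varieties — out of scope by design.

## A worked run

```{r example}
library(juicenir)

config <- pipeline_config(seed = 1)
result <- run_pipeline(config)
result$report          # one row per method: LVs, selected variables,
                       # R2cv / RMSEcv, R2v / RMSEv, relative errors
pipeline_figures(result, "figures")
```

The acceptance script wraps exactly this call and writes the headline
quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
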
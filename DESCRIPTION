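Package: juicenir
Title: Scatter-Corrected VIS/NIR Calibration of Fruit Juiciness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for calibrating fruit juiciness (percent
    juice released on compression) against visible/near-infrared spectra
    (650-1100 nm). Implements nine scatter-correction preprocessing methods
    (normalization, first derivative, detrend, standard normal variate,
    multiplicative scatter correction, probabilistic quotient normalization,
    modified optical path length estimation and correction, linear regression
    correction and orthogonal spatial projection, the latter two combined with
    spectral-ratio variables), competitive adaptive reweighted sampling (CARS)
    for wavelength selection, and single-response partial least squares
    regression evaluated by Monte Carlo cross-validation and external
    validation. Ships a synthetic spectra generator that emulates per-sample
    multiplicative scatter and polynomial additive baselines so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
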
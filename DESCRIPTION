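Package: ramanmcr
Title: Constrained MCR-ALS Unmixing and Classification of Skin Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gray-box analysis of in vivo skin Raman spectra: a synthetic
    skin-Raman generator with known ground truth (pure-component spectra,
    class-dependent concentrations, fluorescence background, etalon ripple,
    target signal-to-noise ratio), preprocessing (asymmetric least squares
    baseline removal, Savitzky-Golay smoothing, cropping, min-max rescaling),
    SVD-based rank suggestion, constrained multivariate curve resolution by
    alternating least squares (SIMPLISMA initialization, fast non-negative
    least squares, equal-area closure, equality-constrained basis spectra),
    and downstream classification of resolved concentration profiles
    (ROC/AUC with DeLong intervals, binary logistic regression, PLS-DA with
    stratified cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
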
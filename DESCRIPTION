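Package: ternspec
Title: Resolution of Overlapped Ternary UV-Vis Mixtures by
    Ratio-Subtraction, Derivative Spectrophotometry and Multivariate
    Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the heavily overlapped ternary drug mixture
    hydroxyzine hydrochloride, ephedrine hydrochloride and theophylline
    from UV-Vis absorption spectra without prior separation.  Implements
    two complementary resolution strategies: ratio-subtraction combined
    with third-derivative spectrophotometry (univariate calibration lines
    at analyte-specific wavelengths), and mean-centred PLS-1 / principal
    component regression on a multilevel multifactor calibration design
    with leave-one-out cross-validation.  Includes ICH-style assay
    validation statistics (recovery, RSD, Student's t, variance-ratio F,
    standard addition) and a Beer-Lambert Gaussian band-model simulator
    that reproduces the spectral geometry the methods rely on, so every
    pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
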
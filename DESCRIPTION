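Package: salivaftir
Title: Chemometric Analysis of Salivary ATR-FTIR Spectra for Diabetes Monitoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for vibrational-fingerprint analysis of saliva by attenuated
    total reflection Fourier-transform infrared (ATR-FTIR) spectroscopy in the
    context of diabetes monitoring. Implements spectral preprocessing
    (rubber-band baseline correction, vector normalization, Savitzky-Golay
    second derivatives), Beer-Lambert band-area quantification with one-way
    ANOVA/Tukey group statistics and Pearson correlation against glycemia,
    ROC-curve diagnostics with Youden cutoff selection, PCA-LDA classification
    with leave-one-out cross-validation, and Ward hierarchical clustering on
    diagnostic spectral regions. A seeded synthetic-cohort generator emulates
    the group structure of a non-diabetic / diabetic / insulin-treated rat
    study so that the complete pipeline runs and is testable without external
    data. Spectra are read and written as CSV or JCAMP-DX.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    ape,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
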
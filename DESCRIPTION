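Package: OneClassSpectra
Title: One-Class Chemometric Screening of Spectral Data for Food Adulteration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Non-targeted screening of powdered-food adulteration from FT-IR and
    FT-NIR spectra using one-class classifiers. Implements data-driven SIMCA
    (PCA class model with chi-square acceptance and outlier boundaries on the
    score and orthogonal distances) and one-class partial least squares
    (unit-response PLS with Hotelling's T-squared and absolute-centered-residual
    limits, Monte-Carlo cross-validation for latent-variable selection),
    together with standard spectral pretreatments (SNV, MSC, normalization,
    Savitzky-Golay smoothing and derivatives), classification metrics, a
    synthetic spectra generator reproducing a two-variety almond-powder
    adulteration study design, and an end-to-end study pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
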
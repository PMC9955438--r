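Package: sersdx
Title: Serum SERS Chemometrics for Benign Gallbladder Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing and multivariate classification of serum
    surface-enhanced Raman spectroscopy (SERS) spectra for discriminating
    gallbladder stones, gallbladder polyps and healthy controls.
    Implements Savitzky-Golay smoothing, adaptive iteratively reweighted
    penalized least squares (airPLS) baseline correction, vector
    normalization, OPLS-DA built on NIPALS with orthogonal signal
    correction, PCA-LDA, stratified k-fold cross-validation,
    permutation-test model validation with R2/Q2 intercepts, one-vs-rest
    ROC/AUC, peak-intensity extraction and one-way ANOVA group comparison,
    together with a synthetic serum-SERS cohort generator for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
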
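Package: nirsdepress
Title: fNIRS Denoising, Feature Extraction and Depression-Severity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support pipeline for grading depression severity from
    prefrontal functional near-infrared spectroscopy (fNIRS) recordings of a
    block-design verbal fluency task. Provides a synthetic cohort generator
    with task-locked hemodynamics and physiological noise, modified
    Beer-Lambert conversion, polynomial detrending, temporal derivative
    distribution repair (TDDR) motion correction, zero-phase Chebyshev type II
    filtering, CEEMDAN decomposition with wavelet-packet thresholding of
    high-frequency modes (CEEMDAN-WPT denoising), extraction of temporal and
    inter-channel correlation features, two-pass recursive feature elimination
    with cross-validation, nested cross-validated classification with four
    model families, and channel-activation statistics from a general linear
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    nnet,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
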
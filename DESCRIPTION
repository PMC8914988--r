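Package: pressureHAR
Title: Human Activity Recognition from Textile Pressure-Sensor Sleeve Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for recognising daily activities from low-resolution (20x10)
    textile pressure-sensor images recorded by an instrumented sleeve. Provides
    a synthetic-data generator emulating multi-subject, multi-round recordings
    with body-size-dependent contact areas and re-wearing offsets; a
    preprocessing pipeline (bilinear upsampling, Gaussian smoothing,
    anthropometric size normalization and exposure-image centre-of-mass
    alignment); a 100-feature static descriptor set (statistical, geometric and
    symmetry features, including Hu invariant moments and contour statistics);
    an evaluation harness with six classical classifiers under stratified
    10-fold and leave-one-subject-out cross-validation with macro-averaged
    metrics and an ablation grid; and a small three-block convolutional
    network, implemented natively, operating on raw frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    randomForest,
    rpart,
    nnet,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
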
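Package: pyratex
Title: Pyramidal Patch Texture Features with Hybrid Chi-Square/NCA
    Selection for Binary Ultrasound Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature-engineering pipeline for binary classification of
    ultrasound-like grayscale images. Images are standardized to 256 x 256,
    decomposed into a five-level average-pooling pyramid, and tiled into 341
    fixed-size 16 x 16 patches. Each patch yields a 292-dimensional hybrid
    descriptor (256-bin local phase quantization histogram plus a 36-value
    histogram of oriented gradients), giving a 99,572-dimensional per-image
    feature vector. A two-stage selector ranks features by a chi-square
    filter, keeps the top 1000, weights them by neighborhood component
    analysis, and sweeps weight-ordered prefixes to minimize cross-validated
    nearest-neighbor error. Five shallow classifiers (k-nearest neighbor,
    linear discriminant, Gaussian naive Bayes, support vector machine,
    decision tree) are tuned by Bayesian optimization with an
    expected-improvement acquisition. A seeded generator of two-phenotype
    speckled synthetic images (parallel echogenic lines vs. dome plus
    midline streak) provides a reproducible stand-in benchmark for the
    private clinical data the method was designed for.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    png,
    e1071,
    rpart,
    pROC,
    jsonlite,
    lhs,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse,
    jpeg,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
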
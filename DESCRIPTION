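Package: protonet
Title: Prototypical Radial Basis Function Networks for Wrist-Worn Tremor Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Parkinson rest-tremor episodes in free-living wrist
    accelerometer recordings with prototypical radial basis function (RBF)
    networks. Provides the full pipeline: anti-aliased downsampling from
    200 Hz to 50 Hz, l1 trend filtering to remove orientation drift,
    changepoint segmentation into approximately stationary pieces, a
    45-dimensional spectral/entropy feature set on non-overlapping 2-second
    windows, MAP inference for Dirichlet process Gaussian mixtures that
    summarise expert-flagged prototypical examples per movement sub-class,
    single- and two-layer prototypical RBF classifiers trained with an
    alternating embedding-gradient scheme, and a leave-one-subject-out
    evaluation harness with specificity-band thresholding, sub-class
    stratified metrics, learning curves and duration-agreement statistics.
    A synthetic free-living cohort generator stands in for restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
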
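Package: phasedeath
Title: Label-Free Cell Death Classification from Quantitative Phase Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating alive, apoptotic and
    necroptotic cells in quantitative phase images from digital holographic
    microscopy. Converts phase delay to optical height, segments full
    field-of-view captures into single-cell crops, purifies experiment-level
    condition labels with a supervised anomaly-detection (SVM) filter, trains
    a transfer-learning style convolutional network (VGG-19 architecture or a
    desk-scale CNN) on balanced, stratified splits, and evaluates with
    per-class accuracy, confusion matrices and one-vs-rest ROC/AUC. Includes
    a seeded synthetic capture generator with planted cell-death morphologies
    so the whole pipeline runs without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
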
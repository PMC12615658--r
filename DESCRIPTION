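Package: locustsel
Title: Locust Detection Pipeline with Artificial Bee Colony Feature
    Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An offline-runnable implementation of a locust-detection
    image-classification pipeline for agricultural monitoring: MSE/PSNR
    image quality filtering, pluggable convolutional backbone feature
    extraction (VGG19-style, ResNet50-style, InceptionV3-style and a
    compact test backbone), linear support-vector feature ranking by
    hyperplane coefficient magnitude, Artificial Bee Colony (ABC) binary
    feature-subset search with cross-validated subset-accuracy fitness, a
    seven-classifier evaluation harness with stratified hold-out and
    k-fold cross-validation, synthetic image and feature-table generators
    with known ground truth, and a desk-scale simulator for the
    accompanying field robot's soil-moisture decision rules and movement
    commands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    e1071,
    class,
    randomForest,
    rpart,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction, Software
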
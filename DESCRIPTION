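Package: dermafuse
Title: Deep Feature Fusion and Selection for Multiclass Skin Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable toolkit for multiclass dermoscopy lesion classification
    pipelines: class-balancing geometric augmentation (vertical flip, horizontal
    flip, 90-degree rotation), a deep-feature extraction contract for fine-tuned
    residual networks tapped at the global average pooling layer (with a fast
    mock extractor for offline testing), serial feature fusion thresholded by the
    standard error of the mean, skewness-controlled feature selection validated
    by a support-vector-regression fitness loop, and a multi-classifier
    evaluation harness reporting confusion matrices and macro-averaged metrics.
    Ships a synthetic-data generator (labelled images and Gaussian class-blob
    feature matrices) so the full pipeline is testable end to end without any
    dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    e1071,
    EBImage,
    MASS,
    xgboost,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
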
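Package: echorobust
Title: Corruption-Robustness Benchmarking of Echocardiographic View Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how ultrasound image artifacts degrade
    automatic classification of apical transthoracic echocardiography (TTE)
    views (A2C, A3C, A4C, A5C). Provides a synthetic phantom generator that
    emulates sector-shaped B-mode clips with class imbalance and intra-clip
    frame correlation; parametric simulators for motion blur, acoustic
    shadowing and multiplicative speckle noise with deterministic seeding and
    calibrated severity grids; frame- and sequence-level evaluation metrics
    (balanced accuracy, macro one-vs-rest AUC, per-class precision/recall/F1);
    sequence-clustered percentile and paired bootstrap inference with
    empirical p-values and Holm step-down adjustment; and orchestration of
    artifact-by-severity degradation curves, failure-case extraction and
    learning curves for pluggable classifiers (a HOG+SVM baseline and a small
    trainable convolutional network).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
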
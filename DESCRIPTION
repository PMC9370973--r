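Package: ppgqc
Title: Motion-Aware Signal Quality Assessment for Wrist Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pulse-wise quality assessment of wrist photoplethysmography (PPG)
    recorded together with tri-axial accelerometry. Band-pass filters the PPG,
    segments it into single pulses with a two-moving-average event detector,
    stratifies pulses by a minute-wise accelerometer activity index, computes
    nineteen per-pulse signal quality indices, selects features by regularized
    neighborhood component analysis with stability voting, and trains and
    evaluates Basic-quality and two High-quality (single-stage and cascaded)
    binary classifiers plus two literature baselines. Includes a synthetic
    PPG + accelerometer cohort generator with ground-truth quality labels and
    simulated raters so the whole pipeline runs end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    nnet,
    randomForest,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
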
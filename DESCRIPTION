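Package: carotidpwa
Title: Pulse Wave Analysis of Carotid Distension Waveforms for Blood
    Pressure Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating systolic blood pressure from carotid
    artery diameter distension waveforms. Implements cross-correlation
    echo tracking of arterial walls in A-mode radio-frequency ultrasound
    frames, extraction of 52 morphological pulse-wave features from the
    distension waveform and its first and second derivatives, and
    per-subject machine-learning calibration (random forest, gradient
    boosting, multiple linear regression) against a mean-value baseline.
    A synthetic-data generator emulates the acquisition protocol (rest,
    cold pressor, post-exercise phases across repeated sessions) with a
    known morphology-to-pressure mapping so every stage of the pipeline
    can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
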
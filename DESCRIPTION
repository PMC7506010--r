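Package: senscore
Title: Estimating Upper-Limb Clinical Scores from Wearable Accelerometer Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Machine-learning pipeline that estimates upper-limb clinical
    scores -- the Fugl-Meyer Assessment (FMA, impairment severity, 0-66) and
    the Functional Ability Scale (FAS, movement quality, 0-5) -- from
    multi-site accelerometer recordings made during eight Wolf Motor Function
    Test tasks. Provides trial segmentation, zero-phase Butterworth
    band-filtering, kinematic magnitude series (displacement, velocity,
    acceleration, jerk), a nine-family feature extractor, correlation-based
    feature selection (CFS) with best-first search, per-task random-forest
    regression, a class-balanced bootstrap random forest, four FMA estimation
    methods of increasing sophistication, a leave-one-subject-out
    cross-validation harness with RMSE, r-squared, bias and per-class error
    analysis, cohort comparison statistics (chi-square, pooled t, Holm
    correction), and a synthetic labelled-cohort generator so the full
    pipeline is testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pracma,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
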
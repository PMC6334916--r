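Package: moodscreen
Title: Wearable-Sensor Screening for Childhood Internalizing Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for screening young children for
    internalizing disorders (anxiety, depression) from a single waist-worn
    inertial measurement unit recorded during a brief mood-induction task.
    Provides complementary-filter orientation estimation and derivation of six
    world-referenced kinematic channels from raw accelerometer/gyroscope
    data, segmentation into the task's three temporal phases, a 29-feature
    time-series descriptor per channel (174 per phase), Davies-Bouldin
    univariate feature selection, leave-one-subject-out cross-validated
    logistic classification with fold-internal standardization, a
    beta-sampled permutation test against chance, a questionnaire-cutoff
    (CBCL T score) comparator, and a synthetic cohort simulator so the whole
    pipeline is testable without real child data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    pROC,
    optparse
Config/testthat/edition: 3
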
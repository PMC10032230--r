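Package: rehabsense
Title: Detection and Classification of Shoulder Physiotherapy Exercise from
    Wrist-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage machine-learning pipeline for monitoring shoulder
    rehabilitation exercise with a single wrist-worn inertial measurement unit.
    Irregularly sampled accelerometer/gyroscope streams are resampled to 50 Hz
    and segmented into overlapping ten-second windows; an out-of-distribution
    detector (KMeans distance, softmax confidence, patient-specific
    k-nearest-neighbour distance, or proxy-class supervised variants) removes
    non-exercise activity under a sensitivity-constrained threshold, and the
    retained windows are classified into exercises or coarser motion groupings
    by a random forest, a fully convolutional network, or a patient-specific
    k-nearest-neighbour model fitted on the patient's own most recent
    supervised session. Includes engineered statistical and learned
    (convolutional embedding) window features, a subject- and session-aware
    cross-validation protocol, and a seeded synthetic cohort generator for
    end-to-end evaluation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
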
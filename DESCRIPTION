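Package: footstrike
Title: Foot Strike Angle Prediction and Classification from Two-Sensor
    Pressure Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating running foot strike from fore/aft
    pressure-insole force traces: a calibrated waveform simulator with known
    foot strike angle, loading-rate based detection of initial contact and
    toe off, extraction of the ten stance-phase impulse, peak-force and
    rate-of-force-development predictors, foot strike angle prediction via a
    published fixed-coefficient regression or trainable models (p-value
    stepwise regression, conditional-inference tree, random forest), foot
    strike pattern classification with the Altman-Davis angular cut-offs,
    and evaluation through error metrics, Bland-Altman agreement and
    three-class confusion-matrix statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
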
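Package: upliftscape
Title: Predicting Uplift Availability and Soaring-Flight Energy Landscapes
    from Static Terrain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking soaring-bird movement data to the
    static structure of the landscape. Segments high-resolution GPS bursts
    into circular soaring, linear soaring and gliding with an
    expectation-maximization binary clustering of vertical speed and turning
    angle; derives overall dynamic body acceleration (ODBA) from tri-axial
    accelerometer bursts and isolates high-altitude flapping as evidence of
    absent uplift; models uplift occurrence from static terrain predictors
    with a cross-validated random forest and maps suitability with
    true-skill-statistic thresholding and extrapolation masking; models
    uplift intensity (positive vertical speed) with generalized additive
    models; and relates daily energy expenditure to predicted uplift
    availability with a linear mixed model. Includes a synthetic-data
    generator that plants a known uplift field in a simulated landscape and
    emulates the tracking devices' sampling schedules, so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    lme4,
    randomForest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
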
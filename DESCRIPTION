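Package: tristep
Title: Gait Analysis of the First Three Steps and Fall-Risk Model
    Development from Pose-Landmark Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Video-keypoint gait analysis of the first three steps of a
    standing-start walk and development of fall-risk prediction models.
    Reads 33-point pose-landmark time series, segments gait cycles from
    vertical ankle-velocity minima, computes a 77-entry spatiotemporal and
    angular feature catalogue with stature normalization, and develops
    sex-stratified logistic fall-risk models via univariate ROC-AUC
    screening, NearMiss undersampling, and an exhaustive 3-5 feature
    combination search under stratified group k-fold cross-validation
    scored by PR-AUC. Includes discrimination metrics with confidence
    intervals and interpretation bands, trial-retest reliability (ICC),
    a Riley-style minimum-sample-size calculator for binary prediction
    models, and a parametric standing-start gait simulator with ground
    truth events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
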
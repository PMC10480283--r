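Package: crtscore
Title: Baseline-MRI Scoring Systems and Multireader Evaluation for
    Rectal Cancer Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements three visual scoring systems used on baseline rectal
    MRI to predict a (near-)complete response to neoadjuvant
    chemoradiotherapy (a 5-point confidence score, a 4-point high-risk
    feature count, and a dichotomised 2-point score), together with the
    complete multireader evaluation machinery: Krippendorff's alpha
    interobserver agreement with nominal and ordinal metrics and missing
    data, reader-averaged ROC/AUC with stratified bootstrap confidence
    intervals, Youden-optimal cutoffs and confusion-matrix metrics, a
    random-intercept linear probability model for reader-experience
    effects fitted by profile REML, and a binomial regression of
    per-patient diagnostic correctness on the chemoradiotherapy-to-surgery
    interval. A calibrated synthetic multireader cohort generator
    (latent patient truth, logistic response link, experience-dependent
    reader perception error) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
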
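Package: radsurv
Title: CT Radiomics and Deep Cox Survival Modelling of Tumour Progression Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end pipeline for predicting progression-free survival after
    EGFR-TKI therapy in advanced non-small-cell lung cancer from pretreatment CT:
    synthetic tumour-phantom cohorts with known prognostic ground truth, isotropic
    resampling and undecimated wavelet decomposition, a 593-feature radiomic panel
    (histogram, GLCM, GLRLM, LBP, shape), two-step feature selection (univariate
    Cox / chi-squared screens plus sequential forward selection), a feed-forward
    Cox partial-likelihood network (DeepSurv) with Breslow baseline for
    personalized survival curves, time-dependent ROC evaluation with bootstrap
    model comparison, and a Weibull reference risk curve classifying each
    patient's risk-of-progression period.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    RNifti,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
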
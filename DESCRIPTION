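Package: copreserve
Title: Multidimensional Temporal Analysis of Center-of-Pressure Signals for
    Compensatory Reserve Assessment in Sarcopenia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing force-platform center-of-pressure (COP)
    recordings from quiet-standing balance tests. Implements a complete
    pipeline from raw six-channel COP time series to sarcopenia-vs-control
    classification and an intra-group "compensatory reserve" variability
    report: per-channel outlier cleaning, origin translation and Z-scoring;
    construction of posture-specific healthy median templates with Grubbs
    screening; banded dynamic time warping deviation features with a
    parameterised cost exponent; fixed-weight LSTM embeddings used as
    deterministic temporal transformers; global statistical descriptors
    (coefficient of variation, linear trend slope, interquartile range);
    hybrid ANOVA-F plus random-forest feature selection with Spearman
    correlation pruning; SMOTE-balanced stratified cross-validation over
    seven classifier families; and quantification of out-of-fold predicted
    probability variability among patients. A synthetic cohort simulator
    with controllable drift, corrective delay and sway dispersion supports
    end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    randomForest,
    ranger,
    e1071,
    rpart,
    caret
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
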
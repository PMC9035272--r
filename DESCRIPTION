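Package: loshurdle
Title: Two-Stage Hurdle Models for Skewed Length-of-Stay Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for predicting highly right-skewed continuous outcomes
    such as in-hospital length of stay (LOS). Implements a two-stage hurdle
    approach that first classifies encounters into short versus prolonged
    stays with a sensitivity-targeted probability cutoff, then regresses
    actual LOS among gate-passing encounters on a truncated training
    subpopulation. Includes a truncated hinge ("customized") evaluation loss,
    MAE/MSE/MRE and stratified variants, outcome transforms (natural log,
    truncation), pluggable base learners (penalized linear models via glmnet,
    random forests via ranger, feed-forward networks via nnet), a train/test
    and cross-validation evaluation harness with calibration slope,
    precision-recall and ROC summaries and percentile bootstrap intervals,
    and a seedable synthetic-cohort generator emulating an elective-surgery
    LOS distribution.
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
    glmnet,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
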
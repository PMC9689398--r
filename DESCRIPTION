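Package: ctgforesee
Title: Predictive Fetal Monitoring from Cardiotocography Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intrapartum cardiotocography (CTG) analysis: FIGO-style
    feature extraction from paired fetal heart rate (FHR) and uterine
    contraction (UC) signals sampled at 4 Hz, including iterative baseline
    estimation, acceleration/deceleration detection and subtyping, contraction
    detection and contraction-relative late-deceleration logic; classification
    of fetal acidosis (umbilical cord pH < 7.2) with grid-searched base
    learners and an abstaining unanimous-vote ensemble with Pareto analysis of
    the coverage/accuracy trade-off; short-horizon recursive LSTM forecasting
    of both channels; and an integrated pipeline that classifies the
    forecasted future to predict the upcoming fetal state. A seeded synthetic
    CTG generator with ground-truth annotations makes every stage testable
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    e1071,
    randomForest,
    nnet,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
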
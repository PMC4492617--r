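Package: srpNTCP
Title: Normal Tissue Complication Probability Modelling of Symptomatic
    Radiation Pneumonitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multivariable normal tissue complication probability
    (NTCP) models for symptomatic radiation pneumonitis after breast
    radiotherapy. Derives dosimetric factors (mean lung dose, relative and
    absolute ipsilateral-lung volumes IV5-IV50 / AIV5-AIV50) from cumulative
    dose-volume histograms, ranks candidate clinical and dosimetric risk
    factors with an L1-penalized logistic regression path (cyclic coordinate
    descent with cross-validated penalty), selects the model size by area
    under the ROC curve subject to Hosmer-Lemeshow calibration, fits the
    final logistic NTCP model with odds ratios and a performance battery
    (AUC, Nagelkerke R2, omnibus likelihood-ratio test, Hosmer-Lemeshow,
    Brier score), and inverts univariate dose-response curves to tolerance
    dose-volume constraints (TV50/TV20). Includes a synthetic cohort
    generator with parametric lung DVHs so the whole pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
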
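Package: tierstack
Title: Multi-Tier Stacked Ensembles for Imbalanced Clinical Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Binary classification for imbalanced tabular clinical risk-factor
    data using a three-tier stacked ensemble: cross-validated base learners,
    an ensemble tier that condenses their out-of-fold predictions through
    fixed combination schemes (averaging, majority vote, maximum, product
    rule) into meta-features, and a generalization tier whose meta-learner is
    trained on those meta-features together with the raw features most
    correlated with the outcome. Includes the surrounding protocol:
    criticality-aware imputation, frequency-based outlier screening on
    concatenated binary codes, SMOTE minority oversampling, mean-cancellation
    normalization, correlation-based feature ranking, a repeated-trial
    evaluation harness with ROC/AUC, a traditional stacked-ensemble baseline,
    and a synthetic generator for preterm-birth-style risk-factor datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
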
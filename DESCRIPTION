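Package: psistack
Title: Stacked Ensemble Prediction of RNA Pseudouridine Sites from
    Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts pseudouridine (Psi) sites in RNA from fixed-length,
    uridine-centred sequence fragments. Implements six sequence encoding
    schemes (sliding-window nucleotide composition, one-hot, nucleotide
    chemical properties, position-specific trinucleotide propensity, and
    position-specific di-/trinucleotide one-hot), chi-square feature
    ranking with incremental feature selection, a feature-scheme
    combination search, and a stacking ensemble classifier that trains a
    logistic-regression meta-learner on out-of-fold base-classifier
    probabilities. Includes a full evaluation harness (sensitivity,
    specificity, accuracy, Matthews correlation, ROC/AUC, stratified
    k-fold cross-validation) and a synthetic-data generator that plants
    class-differential trinucleotide signal so the whole pipeline can be
    exercised without external downloads.
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
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    seqinr,
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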
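Package: speechAD
Title: Speech and Language Feature Battery for Alzheimer's Detection from
    Picture Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts a 509-dimensional battery of lexico-syntactic, acoustic
    and picture-content semantic features from CHAT-format transcripts and
    audio of the Cookie Theft picture-description task, and implements the
    accompanying analysis protocol for Alzheimer's disease detection:
    ANOVA-F top-k feature selection, SVM / neural network / random forest /
    naive Bayes classifiers and linear / ridge MMSE regressors with fixed
    hyperparameters, leave-one-subject-out and stratified 10-fold
    cross-validation with three-seed averaging and majority voting,
    per-feature group differentiation with Bonferroni correction, and a
    synthetic cohort generator that plants known group effects so the whole
    pipeline is testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    igraph,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
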
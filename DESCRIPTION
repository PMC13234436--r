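Package: nacstrat
Title: Multicohort Machine-Learning Stratification of Neoadjuvant
    Chemotherapy Response in Muscle-Invasive Bladder Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a machine-learning workflow for
    predicting response to cisplatin-based neoadjuvant chemotherapy (NAC) in
    muscle-invasive bladder cancer. Provides multicohort transcriptome
    scaling and harmonization (nine scalers including Yeo-Johnson power and
    RankGauss transforms, with a Gaussianity gate and random-forest
    premodeling), data-driven gene-classifier extraction from random-forest
    importance ensembles with mutual-information / variance-inflation-factor
    reduction, a fully enumerated multicohort cross-validation design with
    six evaluation metrics, recursive feature elimination with
    cross-validation (RFECV) plus stepwise optimization of small
    immunohistochemistry marker panels from digital-pathology tables, and
    Kaplan-Meier / log-rank survival stratification of predicted response
    groups. A synthetic-data module with known ground truth replaces patient
    data so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    rpart,
    survival,
    mclust,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    withr
Config/testthat/edition: 3
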
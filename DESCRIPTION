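Package: muellerforest
Title: Mueller Matrix Polarimetry and Random Forest Classification of Skin Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for Stokes-Mueller polarimetry of biological tissue and its
    use in skin-lesion classification. Reconstructs full 4x4 Mueller matrices
    from the six-input-state Stokes measurement protocol, simulates
    class-conditional tissue measurements from standard polarization-optics
    building blocks (diattenuator, retarder, depolarizer) with a hierarchical
    noise model, and classifies normalized Mueller-matrix elements with a
    from-scratch Gini-impurity random forest including the mean-decrease-in-
    impurity feature importance decomposition. Ships the full training
    workflow (minority-class oversampling, stratified repeated k-fold
    cross-validation, hyperparameter grid search) and evaluation metrics
    (confusion matrix, precision/recall/F1, one-vs-rest ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
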
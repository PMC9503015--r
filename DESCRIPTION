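Package: DBTmc
Title: Whole-Image Classification of Microcalcification Clusters in
    Simulated Digital Breast Tomosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study fully automatic, whole-image classification of
    digital breast tomosynthesis (DBT) slices for the presence or absence
    of microcalcification clusters (MCs). Provides a seeded generator of
    VICTRE-like synthetic DBT cohorts with known ground truth (four breast
    density classes, contaminated background, additive calcification
    clusters), the six preprocessing arms built from background
    suppression, total-variation (ROF) denoising, CLAHE contrast
    enhancement and square normalization, proportional slice selection,
    patient-level stratified k-fold cross-validation with reflection and
    rotation augmentation, an AlexNet-derived convolutional network
    (CNN-a, batch normalization in place of local response normalization
    plus an extra max-pooling layer) together with from-scratch AlexNet,
    GoogLeNet, ResNet18 and SqueezeNet layer graphs on a built-in CPU
    training engine, and ROC/AUC evaluation with fold averaging,
    density-stratified testing and t-test model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
biocViews: Classification, Preprocessing
RoxygenNote: 7.3.3
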
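Package: amyloidhex
Title: Balanced-Dataset Amyloidogenicity Classification of Hexapeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of amyloid fibril formation for
    hexapeptides on balanced datasets. Encodes peptides into a 4125-dimensional
    descriptor vector spanning fifteen descriptor families (AAindex positional
    encoding, z-scales, grouped and enhanced grouped amino-acid composition,
    dipeptide deviation from expected mean, grouped dipeptide composition,
    composition/distribution (CTD) descriptors, pseudo and amphiphilic pseudo
    amino-acid composition, quasi-sequence-order and sequence-order coupling
    numbers, and Moreau-Broto, Moran and Geary autocorrelations). Provides
    from-scratch kernel (Gaussian, unbounded support) naive Bayes and
    GentleBoost stump-ensemble classifiers, class balancing by downsampling,
    stratified train/test splitting, k-fold cross-validation, a repeated
    random-rebuild robustness protocol, and the full confusion-matrix metric
    suite (accuracy, sensitivity, specificity, balanced accuracy Q, Matthews
    correlation coefficient, error rate, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    withr,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
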
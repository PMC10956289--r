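Package: ceusdx
Title: Liver-Lesion Malignancy Classification from Contrast-Enhanced
    Ultrasound Cine Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for benign/malignant classification of
    focal liver lesions from contrast-enhanced ultrasound (CEUS) cine loops.
    Reads dual-panel multiframe DICOM loops with sidecar lesion annotations,
    fits five indicator-dilution bolus models (lognormal, gamma-variate,
    LDRW, first-passage-time, lagged normal) to lesion time-intensity
    curves with multi-start nonlinear least squares and best-model
    selection, rejects out-of-plane frames by a 2-sigma residual rule,
    splits loops into phase-labelled mini-loops (arterial, portal-venous,
    late), and classifies them with a natively implemented CNN-LSTM
    (temporal adaptive pooling, bidirectional first LSTM layer, sigmoid
    head, majority-vote case aggregation). Includes a TIC-feature
    gradient-boosted-tree baseline, stratified patient-level
    cross-validation with ROC/AUC metrics, and a ground-truthed synthetic
    CEUS cine-loop simulator so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    xgboost,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
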
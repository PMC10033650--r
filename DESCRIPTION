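Package: milformer
Title: Multiple-Instance Transformer for Predicting Bulk RNA-Seq Expression
    from Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiple-instance-learning pipeline that predicts bulk RNA-seq
    gene expression from H&E whole-slide images while learning a slide-level
    representation usable for subtype classification and content-based slide
    search. Slides are reduced to bags of spatially k-means-clustered tiles,
    tiles are embedded with a pluggable CNN-style backbone, and a transformer
    encoder with a class token is trained with a joint cross-entropy plus
    scaled mean-squared-error objective. Includes expression-table
    preprocessing (median-zero gene filter, log10(1+a) transform, patient-wise
    splits), per-gene correlation reports with Holm-Sidak and
    Benjamini-Hochberg correction, MAE/RMSE/RRMSE error metrics,
    classification metrics with micro ROC-AUC, PCA projection, a
    leave-one-patient-out retrieval evaluation (P@K, AP@K, MAP@K), and
    synthetic-data generators for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    withr,
    EBImage,
    pROC,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
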
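Package: hemafex
Title: Joint Autoencoder Feature Extraction for Hematopoietic Cancer
    Subtype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and multi-class classification for
    hematopoietic cancer subtypes from bulk RNA-seq FPKM expression
    matrices. Implements a deep autoencoder trained jointly on a
    reconstruction loss (mean squared error) and a classification loss
    (cross-entropy or focal loss) whose low-dimensional code serves as
    input features for downstream classifiers; SMOTE oversampling for
    class imbalance; an imbalance-aware evaluation suite (precision,
    recall, specificity, F1, G-mean, index of balanced accuracy,
    confusion matrices, precision-recall curves); a sampling-based
    Shapley-value attribution for biomarker ranking; PCA and NMF baseline
    feature extractors; and a synthetic FPKM data generator with planted
    class-discriminative genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    data.table,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
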
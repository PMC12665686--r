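Package: screformer
Title: Cell-Type Classification from scRNA-seq with an LSH-Attention Reformer Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage (masked-expression self-supervised pre-training, then
    supervised fine-tuning) cell-type classifier for single-cell RNA-seq
    count matrices. The encoder is a Reformer: locality-sensitive-hashing
    attention over the full gene sequence plus reversible residual layers,
    implemented with hand-written forward and backward passes. Includes
    expression binning/tokenization against a gene-embedding vocabulary,
    an AdamW training loop with warm-up, evaluation metrics (accuracy,
    macro F1, one-vs-rest AUC, confusion matrices), stratified splits and
    k-fold cross-validation, sampling-based Shapley gene attribution, and
    a negative-binomial synthetic-data generator with planted marker
    modules for end-to-end testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
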
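Package: midnet
Title: miRNA-Disease Association Prediction from Heterogeneous Network
    Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts candidate miRNA-disease associations by fusing
    network behavior features with intrinsic attribute features. A
    heterogeneous miRNA-protein-disease association network is embedded
    with GraRep (log-shifted k-step transition matrices factorised by
    truncated SVD); miRNA 3-mer sequence composition and MeSH-style
    DAG-based disease semantic similarity supply attribute features.
    Labeled pairs are classified with a random forest and evaluated
    under stratified five-fold cross-validation; candidate miRNAs are
    ranked per disease. Includes a synthetic-world generator with a
    planted group signal so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    randomForest,
    e1071,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
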
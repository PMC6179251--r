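Package: sctransfer
Title: Transfer-Learning Cell-Type Annotation for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cell types in a target single-cell RNA-seq dataset by
    transferring a classifier trained on a previously labeled source dataset.
    Implements a univariate feature-engineering workflow (shared-gene
    alignment, rare-gene removal, pooled-mean and mutual-information gene
    selection, correlation pruning, fixed ordinal expression binning) followed
    by a pre-tuned gradient-boosted tree classifier, in multiclass and
    per-cell-type binary modes with score-threshold detection of unknown cell
    types. Includes dataset summaries (imbalance ratio, sparsity, class
    distribution cosine similarity), evaluation metrics (accuracy,
    sensitivity, specificity, precision, ROC AUC, majority-vote baseline), a
    top-mean linear-regression benchmark, and a synthetic source/target pair
    simulator with controllable library depth, dropout and gene-universe
    mismatch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
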
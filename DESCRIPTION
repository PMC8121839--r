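Package: CellTreeLearn
Title: Hierarchical Progressive Learning of Cell Identities from Annotated
    Single-Cell Datasets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns a classification tree over cell populations by
    reciprocally matching labels across multiple annotated single-cell
    RNA-seq datasets. Per-node local classifiers (linear or one-class
    support vector machines on informative principal components) are
    trained with the siblings policy, unseen populations are rejected by
    thresholding the PCA reconstruction error, and new datasets are folded
    into the tree progressively through confusion-matrix based reciprocal
    matching (perfect match, split, merge, new population). Includes
    hierarchical F1 evaluation, k-fold cross-validation harnesses, and a
    negative-binomial simulator for hierarchically structured benchmark
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'CellTreeLearn-package.R'
    'utils.R'
    'tree.R'
    'pca.R'
    'classifiers.R'
    'hierarchy.R'
    'matching.R'
    'update.R'
    'evaluation.R'
    'simulate.R'
    'io.R'
biocViews: SingleCell, Classification, Transcriptomics
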
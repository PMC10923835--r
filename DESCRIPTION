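Package: cassidi
Title: Cluster Similarity Scoring and Distinction Index for Paired
    Single-Cell Datasets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Matches clusters between two independently clustered
    single-cell RNA-seq datasets using a weighted, uniqueness-aware
    Jaccard similarity over positive marker genes (the cluster
    similarity score, CSS), and scores every (clustering resolution,
    number of principal components) parameter pair with a distinction
    index (DI) so that clustering conditions can be ranked from best to
    worst. Includes a lightweight clustering and marker-detection
    backend, the Nebula comparative-marker visualization, and a
    negative-binomial simulator of genotype-paired count matrices with
    planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    scran,
    igraph,
    irlba,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, Clustering, GeneExpression, Software
RoxygenNote: 7.3.3
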
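Package: hiermarkers
Title: Hierarchical Marker Gene Selection for Clustered Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects marker genes for clustered scRNA-seq data in a
    hierarchical manner. A heatmap block score quantifying undesirable
    off-diagonal marker expression drives an agglomerative grouping of cell
    clusters inside a divisive hierarchy, yielding split-specific markers
    found by one-vs-rest Wilcoxon tests, an assembled zero-masked feature
    matrix for visualization and classification, and an evaluation harness
    (within-dataset KNN classification and cross-dataset cell-type mapping).
    Includes a seeded negative-binomial simulator of hierarchically
    structured cell populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    pheatmap,
    uwot
Suggests:
    testthat (>= 3.0.0),
    optparse,
    class,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
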
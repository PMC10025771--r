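Package: SpotFuse
Title: Multimodal Network Fusion for Spatial Transcriptomics Spot Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates sequencing-based spatial transcriptomics data with the
    matched H&E histology image. A Markov-random-field segmentation of the
    grayscale image yields spot-level pixel-label distributions and a
    histopathological similarity network (symmetric Kullback-Leibler
    divergence); a shared-nearest-neighbor graph in PCA space yields a
    transcriptomic similarity network; both are fused with spot adjacency
    (Manhattan array distance) into a single weighted spot graph. Spatial
    clusters are identified on the fused graph by random-walk-distance
    agglomerative community detection with an automatic modularity cut, and
    gene expression is enhanced by neighborhood smoothing and iterative
    dropout filling. Includes simulators for permeabilization diffusion
    (Fick's first law with a Gaussian spatial kernel) and dropout, detectors
    for spatially differentially expressed genes with a spatial enrichment
    score, the standard clustering evaluation statistics (ARI, NMI,
    maximum-matching accuracy, modularity Q), and a fully synthetic
    Visium-like fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    mclust,
    png,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
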
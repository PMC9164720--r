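Package: spatiomap
Title: Integrating Spatial and Single-Cell Transcriptomics by Multimodal
    Intersection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping single-cell RNA-seq cell types onto
    microarray-based spatial transcriptomics of developing tissue.
    Implements quality-control filtering, log-CP10K normalization,
    PCA embedding and shared-nearest-neighbour graph clustering for
    both modalities; one-vs-rest marker detection (Wilcoxon rank-sum
    or a bimodal likelihood-ratio test) and threshold-based marker
    gene-set extraction; multimodal intersection analysis (MIA), the
    one-sided hypergeometric overlap of cell-type-specific and
    region-specific gene sets used to label spatial clusters;
    marker-restricted non-negative least-squares spot deconvolution
    with a minimum-contribution filter and per-region fraction
    aggregation; weighted gene co-expression network analysis with
    soft-threshold selection, topological-overlap module detection,
    module eigengenes, module-region correlation and hub-gene ranking;
    ligand-receptor matching scores with a permutation null; a
    weighted Kolmogorov-Smirnov gene-set enrichment statistic and
    hypergeometric over-representation analysis; plus a synthetic
    paired-modality data generator with known ground truth for
    validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    pracma,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
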
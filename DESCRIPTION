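Package: chromfusion
Title: Chromatin Profiling Analysis of Fusion-Oncoprotein Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of antibody-tethered chromatin profiling
    (CUT&RUN / CUT&Tag) experiments designed around dual N-terminal /
    C-terminal antibody profiling of the KMT2A protein in leukemia.
    Implements the N-over-C ratio (NCR) statistic with ECDF shrinkage and
    two-component Gaussian-mixture classification of peaks into wild-type
    versus fusion-oncoprotein binding sites; bivalent (H3K4me3 + H3K27me3)
    promoter calling from TSS-window counts; bulk chromatin-landscape
    embedding with lognormal-ECDF count filtering, PCA/t-SNE and
    density-peak clustering; and single-cell chromatin analysis (fragment
    QC, genome binning, latent semantic indexing, UMAP, diffusion-imputed
    gene scores, normalized dispersion, and covariance grouping of gene
    programs). Ships seeded synthetic-data generators with planted ground
    truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    Matrix,
    data.table,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rtsne,
    uwot,
    irlba,
    RANN,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
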
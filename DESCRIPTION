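Package: ptmDynamics
Title: Temporal PTM Quantification, Affinity-Propagation Clustering and
    Acetylation-Phosphorylation Crosstalk Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of quantitative post-translational modification (PTM)
    dynamics from multiplexed reporter-ion (iTRAQ) or SILAC experiments.
    Reads peptide-level quantification tables into a SummarizedExperiment-
    based container, corrects per-channel loading bias by mean-ratio
    normalization, converts intensities to temporal log2 fold-change
    profiles, clusters profiles by affinity propagation with BIC model
    selection, classifies early acetylation responses, and quantifies
    deacetylase-inhibitor crosstalk with the fold-change-ratio (FCR)
    statistic and per-site significance tests. Includes a calibrated
    synthetic-data generator with a ground-truth ledger so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, Clustering, TimeCourse, Software
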
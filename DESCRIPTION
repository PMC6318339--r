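Package: mucosaAtlas
Title: Region-Resolved Stomach Mucosa Proteome Atlas, Reference Intervals
    and Outlier-Based Tumor Subtyping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for region-resolved label-free proteomics of
    the human stomach mucosa. Starting from protein-by-sample iBAQ abundance
    matrices and peptide-evidence tables, the package normalizes abundances
    to fraction-of-total (FOT/iFOT), applies high-confidence detection
    filters, computes detection-frequency atlas statistics (core proteome,
    region-specific proteins, proximal/distal section structure, section
    markers, co-expression modules, per-protein CV), builds per-protein
    percentile reference intervals from a normal cohort with upper limit
    P90 + 3*(P90 - P10), calls outlier proteins in query samples, and
    discovers tumor subtypes from outlier features by resampling consensus
    clustering. A synthetic cohort generator with planted ground truth
    (seven anatomical regions, two stomach sections, tumor/tumor-nearby
    pairs, outlier subtypes) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
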
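Package: plasmatrace
Title: Single-Cell Transcriptome Heterogeneity and Extramedullary
    Metastasis Modelling for Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Smart-seq2 single-cell FPKM expression
    matrices from multiple-myeloma patients. Provides quality-control
    filtering of cells and transcripts, one-way ANOVA calling of
    patient-specific immunoglobulin genes, differential expression between
    clonal circulating plasma cells (CPCs) and bone-marrow myeloma cells
    (BMMCs) with a conjunctive cross-patient rule, silhouette-selected
    hierarchical clustering of BMMCs into FAM46C-low/high subclones, and a
    correlation-based single-cell model of extramedullary metastasis
    (best-Pearson-match CPC-to-BMMC assignment, per-cell metastasis rates
    M_j = C_j / C_p, and per-subclone contribution fractions). A synthetic
    data generator plants the corresponding structure (patient-specific
    immunoglobulin genes, FAM46C-low subclusters with depressed global
    transcriptome, CPCs copied from designated source cells with noise and
    dropout) so the whole pipeline can be exercised and validated without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
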
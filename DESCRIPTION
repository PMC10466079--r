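Package: proteopipe
Title: Differential Analysis Pipelines for Quantitative Proteomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tandem analysis workflows for label-free quantitative
    proteomics. Reads protein-group, peptide and modified-peptide
    quantification tables (wide MaxQuant-style or long DIA-style),
    filters on identification flags and missing occupancy, applies
    variance-stabilizing normalization, imputes missing values under
    left-censored (MNAR) or random (MAR) assumptions, optionally
    re-aggregates peptide quantities to protein abundances (Tukey
    median polish, robust regression or total sum), and tests
    contrasts with an empirical-Bayes moderated t-test with
    Benjamini-Hochberg FDR control. Downstream function mining covers
    hypergeometric over-representation analysis and preranked gene-set
    enrichment against local GMT collections, fuzzy c-means clustering
    of expression patterns, and induced-subnetwork extraction from
    local STRING-format edge lists. Includes seeded synthetic-data
    generators with known ground truth and a command-line interface
    that writes a machine-readable run log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    e1071,
    optparse
Config/testthat/edition: 3
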
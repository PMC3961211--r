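Package: isletpop
Title: Population-Structure, Runs-of-Homozygosity and Selection Scans for
    Isolate Cohorts
Version: 0.1.0
Authors@R:
    person("isletpop", "developers", email = "isletpop@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for SNP-array population genetics of isolate
    cohorts: quality control (call rate, minor allele frequency,
    Hardy-Weinberg), structure statistics (PCA, genomic-control inflation
    factor, Hudson and inbreeding-robust Fst estimators, per-sample genomic
    inbreeding coefficients), a sliding-window runs-of-homozygosity caller
    with F_RoH summaries, and an EHH/iHS positive-selection scan with
    permutation-corrected region enrichment.  Includes a Balding-Nichols
    synthetic-data generator with planted autozygous tracts and planted
    selective sweeps so every stage is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    Rcpp,
    stats,
    tools,
    utils,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
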
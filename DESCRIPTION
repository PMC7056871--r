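Package: miromics
Title: Multi-Omics Association Analysis of miRNA-Related Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Candidate-based multi-omics association pipeline linking
    microRNAs to cardiometabolic traits. Builds miRNA-related genomic
    regions (precursor, mature, +/- flank), maps SNPs and CpGs into them,
    tests annotated SNPs against GWAS summary statistics with LD-pruning
    based Bonferroni correction, runs a mixed-model EWAS on miRNA-annotated
    CpGs, normalizes plasma miRNA counts (log2 CPM) with an antitonic
    mean-SD fit deriving the lower limit of quantification, tests
    expression-trait associations, cross-references me-QTL and miR-eQTM
    catalogs, and integrates the three evidence layers into a prioritized
    miRNA table. Includes a synthetic-cohort generator with planted,
    recoverable effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    lme4,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
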
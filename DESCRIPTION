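Package: bgeval
Title: Evaluation Toolkit for Blended Genome-Exome Sequencing Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality-control and benchmarking pipeline for blended genome-exome
    (BGE) sequencing designs, which combine deep whole-exome with low-pass
    whole-genome data in one library. Provides exome genotype/site/sample QC
    filters, batch-wise imputation merging with weighted allele-frequency and
    INFO-score corrections, imputation-accuracy metrics against array truth
    (non-reference concordance and MAF-binned aggregate R squared), local-ancestry
    stratified accuracy, and exonic copy-number-variant recall/PPV benchmarking
    with quartet de novo validation. Includes a synthetic admixed-cohort
    generator (Balding-Nichols divergence, exponential ancestry tracts, binomial
    read-resampling posteriors) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
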
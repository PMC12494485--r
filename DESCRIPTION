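Package: crustvir
Title: Metagenomic and Metaviromic Island Detection and Virus-Host
    Profiling for Glacier Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing read-recruitment signatures of
    host-virus dynamics in environmental metagenomes, developed around
    glacier weathering-crust communities. Implements mismatch-filtered
    coverage profiling, two-regime detection of metagenomic and
    metaviromic islands (under-recruited genomic stretches), island-gene
    eggNOG/COG functional profiling, viral contig screening and vOTU
    retention rules, MAG quality tiering, multi-classifier consensus
    viral taxonomy, virus-host association specificity typing, auxiliary
    metabolic gene curation, and TPM abundance normalisation. A seeded
    synthetic-data generator plants coverage islands and taxonomy truth
    so every stage is testable without raw reads, and a pipeline runner
    orchestrates the stages with a reproducible manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    withr,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
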
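Package: fsgsprio
Title: Inheritance-Aware Variant Prioritization and ACMG Classification
    for FSGS Exome Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for diagnostic exome analysis of
    focal segmental glomerulosclerosis (FSGS) cohorts. Provides a
    gene-panel model with per-gene inheritance modes, annotated-VCF
    ingestion, a five-criteria variant prioritization cascade (coding
    consequence, read depth, panel membership, inheritance-mode-aware
    allele-frequency thresholds, and a mono-/biallelic zygosity rule),
    an ACMG/AMP evidence-combining classifier, cohort-level diagnostic
    yield statistics, and a seeded synthetic-cohort simulator for
    end-to-end validation without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
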
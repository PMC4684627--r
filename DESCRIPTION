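Package: hlhpanel
Title: Targeted Gene Panel Diagnostics for Hemophagocytic
    Lymphohistiocytosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for targeted amplicon-panel sequencing of
    the twelve genes implicated in hemophagocytic lymphohistiocytosis
    (HLH) and related lymphoproliferative disorders. Provides amplicon
    coverage quality control, detection of large homozygous and
    hemizygous exonic deletions from normalized read depth, a variant
    prioritization cascade (consequence class, minor allele frequency,
    in-silico damaging predictions, exact Hardy-Weinberg filtering),
    zygosity- and inheritance-aware molecular diagnosis assignment,
    validation sensitivity with Wilson score confidence intervals,
    rare-variant carrier-burden analysis for population cohorts, and a
    seeded synthetic-data generator so every stage is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
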
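Package: metdriver
Title: Somatic Variant Prioritization and Survival Analysis for Matched
    Primary/Metastatic Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate metastasis driver genes from annotated
    somatic variant tables of matched primary/metastatic tumor pairs.
    Variants are classified as deleterious by a four-criterion filter
    (read depth, functional class, East-Asian population frequency, and
    predicted pathogenicity via a 15-tool consensus vote with
    type-specific routing through VEST-Indel scores and gene
    haploinsufficiency ratings); susceptible genes are called by patient
    recurrence within each tumor group; and mutation-stratified survival
    is compared with an exact two-tailed Wilcoxon rank-sum test,
    Kaplan-Meier curves, and the log-rank test. A seeded synthetic cohort
    generator with known ground truth makes every pipeline stage testable
    without access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
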
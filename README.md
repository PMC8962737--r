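# metdriver

Prioritization of candidate metastasis driver genes from whole-exome
somatic variant calls in matched primary/metastatic tumor pairs, with
mutation-stratified survival analysis.

The package is aimed at cancer-genomics analysts who have annotated
somatic variant tables (ANNOVAR-style, one row per variant per sample)
for a small paired cohort and want a reproducible, auditable path from
those tables to a short list of candidate driver genes and a survival
read-out — without re-running any caller or predictor.

## What it computes

**1. Deleterious classification.** Each variant passes a gate —
sequencing depth > 10, functional class among {nonsynonymous SNV,
frameshift indel, non-frameshift indel, stopgain, stoploss}, East-Asian
population frequency ≤ 1% (missing counts as rare) — and is then routed
by class:

- *nonsynonymous SNV*: deleterious iff at least 13 of 15 registered
  pathogenicity predictors (SIFT, PolyPhen-2 HDIV/HVAR, LRT,
  MutationTaster, MutationAssessor, FATHMM, PROVEAN, VEST3, MetaSVM,
  MetaLR, M-CAP, CADD, FATHMM-MKL, fitCons) vote damaging;
- *frameshift indel / stopgain*: deleterious iff the gene is
  haploinsufficiency-rated (default rating "3") **or** VEST-Indel score
  ≥ 0.85 with p ≤ 0.01;
- *non-frameshift indel*: deleterious iff the VEST-Indel thresholds hold;
- *stoploss*: always retained (read-through extends the protein).

Every verdict carries a reason trail, so the filter is auditable row by
row.

**2. Gene recurrence.** A gene is *susceptible* in a tumor group when at
least 2 patients of that group carry a deleterious mutation in it;
"shared" genes meet the threshold in both the primary and the metastatic
group.

**3. Survival.** Patients are stratified by mutation status of a gene;
DFS is compared with an exact two-tailed unpaired Wilcoxon rank-sum test
(full enumeration of all C(n+m, n) rank assignments; two-tailed
p = 2·min(P(U ≤ u), P(U ≥ u)) capped at 1; mid-rank normal approximation
under ties). Kaplan–Meier curves, the log-rank test, and survival-gain
at a time point support expression-stratified comparisons on synthetic
or user-supplied tables.

**4. Synthetic cohorts.** `simulate_cohort()` generates matched "-P"/"-M"
pairs with class-conditional predictor calls, VEST-Indel Beta scores,
negative-binomial depths, and exponential relapse times with a driver
hazard ratio — with full ground truth, so the whole pipeline is testable
without protected data.

Small assay formulas (tumor volume 0.5·L·W², 2^−ΔΔCt fold change,
wound-healing %, growth-rate %, AOD = IOD/Area) are included as pure
helper functions.

## Worked example

The package bundles a nine-patient matched-pair cohort with ten FLNA
deleterious variants (also under `inst/extdata/` as TSV):

```r
library(metdriver)

ex <- example_cohort()
verdicts <- classify_variants(ex$variants)
rec <- call_susceptible(tally_gene_patients(verdicts))
rec[, c("gene", "n_primary", "n_metastatic", "shared")]
#>   gene n_primary n_metastatic shared
#> 1 FLNA         5            4   TRUE

s <- stratify_by_mutation(ex$clinical, verdicts, "FLNA", "primary")
wilcoxon_rank_sum(s$mutant, s$wildtype)
#> Two-tailed unpaired Wilcoxon rank-sum test (exact_enumeration)
#>   n = 5 (mean 56)  vs  m = 4 (mean 23.25)
#>   U = 2, p = 0.0634921
```

Reading: FLNA carries deleterious mutations in 5/9 primary and 4/9
metastatic tumors, so it is susceptible in both groups. Patients whose
primary tumor carries a deleterious FLNA mutation have mean DFS of 56
months versus 23.25 months for wild-type patients (ratio ≈ 2.4), and the
exact rank-sum p-value is 8/126 ≈ 0.063 — the mutation is associated
with *longer* disease-free survival in this small cohort.

The same analysis can be driven by a YAML config:

```r
run_pipeline(list(
  inputs = list(
    variants  = system.file("extdata", "example_flna_variants.tsv", package = "metdriver"),
    clinical  = system.file("extdata", "example_clinical.tsv",      package = "metdriver"),
    hi_table  = system.file("extdata", "example_hi_table.tsv",      package = "metdriver")),
  survival = list(genes = "susceptible", group = "primary"),
  output_dir = "report"))
```

which writes `variant_audit.tsv`, `gene_recurrence.tsv`,
`survival_comparisons.tsv`, `summary.json` and a run manifest. A thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`.

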
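---
title: "Prioritizing metastasis driver genes from matched tumor pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing metastasis driver genes from matched tumor pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metdriver)
```

## The problem

In a paired-tumor design, each breast-cancer patient with locoregional
recurrence contributes two whole-exome-sequenced samples: the primary
tumor ("-P") and the metastatic tumor ("-M"). The analytic question is
which genes plausibly drive metastasis. The working assumptions are that
driver mutations are functionally harmful ("deleterious") to the protein,
that a real driver recurs across patients, and that mutation status
should leave a footprint in disease-free survival (DFS). `metdriver`
turns those assumptions into a three-stage pipeline over annotated
variant tables: a deleteriousness filter, a recurrence screen, and a
mutation-stratified survival comparison. A seeded synthetic-cohort
generator with known ground truth backs every stage with testable
expectations.

## The deleteriousness filter

A variant must first pass three gates:

| gate | rule | default | note |
|---|---|---|---|
| depth | `depth > min_depth_exclusive` | 10 reads | strict inequality |
| class | class in `allowed_classes` | the five non-synonymous exonic classes | synonymous excluded |
| rarity | `exac_eas_freq <= max_pop_freq` | 1% (East-Asian reference panel) | inclusive; missing passes |

All comparator directions follow the way such thresholds are
conventionally printed: the depth bound is exclusive, frequency and
VEST bounds inclusive. A variant absent from the population database is
treated as rare (`missing_freq_passes = TRUE`); the switch exists
because absence-of-evidence is a judgement call, but for somatic calls
in a small cohort absence overwhelmingly means "not polymorphic".

Past the gate, the decision routes by functional class:

* **Nonsynonymous SNVs** are judged by consensus across a fixed registry
  of 15 pathogenicity predictors. "Damaging" conventions per tool follow
  the dbNSFP categorical codes (e.g. SIFT `D`; PolyPhen-2 `D`/`P`;
  MutationTaster `A`/`D`; MutationAssessor `H`/`M`) and score thresholds
  for the score-only tools (VEST3 ≥ 0.5, CADD phred ≥ 20, fitCons
  ≥ 0.7); all are overridable. A variant is deleterious when at least
  `min_votes = 13` of the 15 vote damaging — the strict reading of
  "more than twelve". A missing prediction counts as a non-damaging
  vote and the denominator stays 15: with no stated missing-data rule,
  the conservative choice shrinks the deleterious set rather than
  inflating it.
* **Frameshift indels and stopgains** truncate the protein; their harm
  is primarily a dosage question, so the primary criterion is the
  gene's haploinsufficiency rating (accepted set defaults to rating
  "3", sufficient evidence). VEST-Indel (score ≥ 0.85 and p ≤ 0.01) is
  accepted as an alternative line of evidence; the two combine by OR.
  Whether a strong in-silico score should rescue a gene without dosage
  evidence is genuinely open — OR-semantics honors both criteria
  without inventing a precedence, and users who want
  haploinsufficiency-only behavior can clear the VEST thresholds to
  impossible values.
* **Non-frameshift indels** have only VEST-Indel available.
* **Stoploss** variants are retained unconditionally once past the
  gate: read-through appends sequence to the protein and is treated as
  inherently damaging.

Every verdict records a `route` and an ordered reason trail
(`gate_pass;votes=13/15(min=13)` and the like), so any downstream count
can be audited back to individual criteria. One deliberate non-rule:
`min_votes` has no enforced upper bound, so setting it above the
registry size is a legitimate way to switch the SNV route off entirely.

## Recurrence

`tally_gene_patients()` counts *patients*, not variant rows: a patient
with two qualifying variants in the same gene and group counts once. In
this paired design each patient contributes exactly one sample per
group, so "at least two samples of a tumor group" and "at least two
patients" coincide; a `by = "sample"` switch exists for unpaired data.
`call_susceptible()` applies the threshold (`min_patients = 2`) per
group; the default `mode = "shared"` requires it in both groups, which
is the reading that produces a compact shared driver list, while
`mode = "either"` gives the union reading. Both are one flag apart
because the narrative phrasing of such criteria is often ambiguous;
shared output is always a subset of either output.

## Survival comparisons

`stratify_by_mutation()` partitions the cohort by deleterious-mutation
status of one gene in one tumor group, and the two DFS samples are
compared with an exact two-tailed unpaired Wilcoxon rank-sum test. The
progression-free survival figure reported for such cohorts is, in
practice, the DFS column of the clinical table — the only time variable
collected — and that is how this package reads it.

Conventions, since the test's name alone under-determines it:

* With `n + m <= exact_limit` (default 12) and no ties, the null
  distribution of U is built by full enumeration of all
  `choose(n+m, n)` rank assignments; the two-tailed p-value is
  `2 * min(P(U <= u), P(U >= u))`, capped at 1. This matches the
  classical exact two-sided convention and agrees with
  `wilcox.test(exact = TRUE)` to machine precision (property-tested on
  1,000 random tie-free samples).
* Ties or larger samples switch to the mid-rank normal approximation
  with tie-corrected variance and continuity correction. Zero rank
  variance (all values identical) returns p = 1.
* The reported U is `min(U_x, U_y)`.

On the bundled nine-patient cohort the full chain gives mutant DFS
{62, 80, 72, 42, 24} vs wild-type {28, 22, 38, 5}, means 56.0 and 23.25
(23.3 at one decimal), U = 2 and exact p = 8/126 ≈ 0.0635 — computed,
not transcribed, by the example below.

```{r example}
ex <- example_cohort()
verdicts <- classify_variants(ex$variants)
s <- stratify_by_mutation(ex$clinical, verdicts, "FLNA", "primary")
wilcoxon_rank_sum(s$mutant, s$wildtype)
```

The Kaplan–Meier estimator and log-rank test are implemented locally
(the product-limit form and the standard one-degree-of-freedom
observed-minus-expected statistic) so that expression-stratified
survival comparisons can run on synthetic or user-supplied tables
without an external service; the test suite cross-checks both against
the `survival` package. `survival_gain_at()` reports
`S_A(t) - S_B(t)` using step-function values, with a truncation warning
beyond both curves' follow-up. Multiple-testing correction across a
several-gene survival screen is deliberately not applied by default (a
raw-p screen is what the recurrence design calls for); p-values are
reported so users can adjust as they see fit.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, not raw sequencing:

* matched "-P"/"-M" samples per patient; driver-mutant patients
  (probability `driver_mutation_prob`, or an exact
  `n_driver_patients`) carry one truly deleterious driver variant in
  each sample; passengers arrive as Poisson(`passenger_rate = 30`)
  benign variants per sample — a deliberately scaled-down variant load
  that keeps cohort-scale tests fast while exercising every route;
* predictor calls are conditionally independent given the true class,
  damaging with probability 0.95 (deleterious) or 0.10 (benign) per
  tool — which makes the consensus sensitivity at 13 votes an exact
  binomial tail, `P(Bin(15, 0.95) >= 13) ≈ 0.964`, an analytic
  operating point the tests verify empirically;
* VEST-Indel scores are class-conditional Betas (deleterious
  Beta(9, 1), benign Beta(2, 8); p-values Beta(1, 50) vs uniform) —
  high but imperfect separation at the default thresholds;
* read depth is negative binomial (mean 80, dispersion 5), so a small
  fraction of variants genuinely fails the depth gate;
* a fraction (`freq_spike_prob = 0.10`) of benign variants receives a
  common population frequency, exercising the rarity gate;
* DFS is exponential with baseline hazard 0.02/month and the driver
  hazard ratio (default 0.4, i.e. driver mutations extend relapse-free
  time roughly in the ratio seen in the worked example); censoring is
  independent exponential with its rate chosen so the expected censored
  fraction equals `censoring_rate`;
* the generator also emits a haploinsufficiency table (drivers rated
  "3", passengers lower or unrated), reflecting that established driver
  genes typically carry dosage-sensitivity evidence; without it,
  truncating driver variants would depend solely on the VEST p-value
  draw, whose Beta(1, 50) distribution clears p ≤ 0.01 only about 39%
  of the time — an intentionally imperfect margin for a criterion that
  is meant to be secondary.

What the generator does **not** emulate: correlation between predictor
tools (real tools share training data and features, so real consensus
votes are more dispersed than binomial), mutational signatures, gene
length and expression covariates of mutation rate, subclonal structure,
and non-exponential hazards. Passing tests therefore demonstrate that
the pipeline's logic and statistics behave as designed under a clean
generating model — not that the filter's operating point transfers
unchanged to real cohorts.

## Numerical and validation choices

* All boundaries are asserted at their exact values in the tests (depth
  10 fails, 11 passes; frequency 0.01 passes; VEST 0.85/0.01 passes).
* Verification problem sizes, chosen to give tight analytic error bars
  while keeping the default suite in the tens of seconds: 1,000 random
  samples for the exact-p oracle and 1,000 random variants for the
  classifier oracle; 2,500 variants per class for the binomial
  operating point (3 standard errors); 500 null replicates at
  n = 200/arm for log-rank type-I error and 200 replicates at hazard
  ratio 3, n = 100/arm for power; Kaplan–Meier closed-form checks at
  n = 500–2,000 with 3-standard-error tolerances; driver recovery over
  100 seeds at 6/20 mutant patients.
* Determinism: every stochastic routine takes or derives from an
  explicit seed; report files contain no timestamps and are
  byte-identical across runs (the manifest isolates its timestamp, and
  its config hash excludes the output directory).
* Degenerate inputs fail loudly with named errors: empty strata,
  no-event log-rank input, negative DFS, duplicated patient ids,
  missing mandatory columns.

## Limitations

The recurrence screen is a plain count threshold — no background
mutation model (MutSigCV-style significance is out of scope), so gene
length and mutability confound it exactly as they do any count-based
screen. The survival comparison on nine patients is descriptive; the
exact test controls its level but nothing corrects for having screened
several genes. Cohort-scale conclusions (total variant yields,
specific gene lists from real data) require the original sequencing
data and are outside what a synthetic cohort can certify.
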
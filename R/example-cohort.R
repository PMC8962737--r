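#' Bundled example cohort: nine matched primary/metastatic pairs with FLNA
#' mutations
#'
#' A small worked-example cohort of nine breast-cancer patients with
#' locoregional recurrence, each contributing a primary ("-P") and a
#' metastatic ("-M") tumor sample. The clinical table carries age, TNM
#' stage, receptor status (ER/PR/HER2) and disease-free survival in
#' months; the variant table holds the ten FLNA deleterious mutations
#' called across the cohort (three missense SNVs, three frameshift
#' deletions, four non-frameshift deletions), with predictor calls and
#' VEST-Indel fields pre-set so that [classify_variants()] marks all ten
#' deleterious under the default filter. The same tables ship as TSV under
#' `inst/extdata/` (`example_clinical.tsv`, `example_flna_variants.tsv`).
#'
#' @return List with `variants` and `clinical` data.frames.
#' @export
example_cohort <- function() {
  clinical <- data.frame(
    patient_id = paste0("Patient", 1:9),
    age = c(56, 56, 46, 44, 68, NA, NA, 58, 30),
    tnm = c("T2N2M0", "T2N0M0", "T3N2M0", "T1N0M0", "T1N0M0", "T1N0M0",
            "T1N0M0", "T2N0M0", "T1N0M0"),
    er = c("++", "+", "++", "++", "+++", "-", "-", "++", "-"),
    pr = c("++", "-", "++", "++", "-", "+", "-", "+", "+"),
    her2 = c("-", "-", "-", "-", "++~++", "++", "+++", "-", "-"),
    dfs_months = c(62, 80, 28, 72, 22, 38, 42, 24, 5),
    event = TRUE,
    stringsAsFactors = FALSE
  )

  v <- data.frame(
    sample_id = c("Patient1-M", "Patient1-M", "Patient2-M", "Patient6-M",
                  "Patient8-M", "Patient1-P", "Patient2-P", "Patient4-P",
                  "Patient7-P", "Patient8-P"),
    start = c(154360534L, 154362486L, 154359888L, 154362486L, 154362486L,
              154361680L, 154362486L, 154366374L, 154354220L, 154352600L),
    end = c(154360570L, 154362491L, 154359891L, 154362491L, 154362491L,
            154361687L, 154362491L, 154366374L, 154354220L, 154352600L),
    ref = c("GCGGGCGGGGGAGCCCGCACTGCCTCCCTGCAGCCCC", "TGTCAT", "TGGC",
            "TGTCAT", "TGTCAT", "GCCAGACA", "TGTCAT", "C", "C", "G"),
    alt = c("-", "-", "-", "-", "-", "-", "-", "T", "T", "A"),
    variant_class = c("frameshift_indel", "nonframeshift_indel",
                      "frameshift_indel", "nonframeshift_indel",
                      "nonframeshift_indel", "frameshift_indel",
                      "nonframeshift_indel", "nonsynonymous_SNV",
                      "nonsynonymous_SNV", "nonsynonymous_SNV"),
    aa_change = c("P1075fs", "831_833del", "A1274fs", "831_833del",
                  "831_833del", "V976fs", "831_833del", "G388S", "V1822M",
                  "S2144L"),
    stringsAsFactors = FALSE
  )
  parsed <- parse_sample_id(v$sample_id)
  v$patient_id <- parsed$patient_id
  v$tumor_group <- parsed$tumor_group
  v$chrom <- "X"
  v$gene <- "FLNA"
  v$depth <- 100L
  v$exac_eas_freq <- NA_real_

  is_snv <- v$variant_class == "nonsynonymous_SNV"
  rules <- default_predictor_rules()
  for (tool in names(rules)) {
    v[[tool]] <- ifelse(is_snv, damaging_call_for(rules[[tool]]),
                        NA_character_)
  }
  v$vest_indel_score <- ifelse(is_snv, NA_real_, 0.95)
  v$vest_indel_p <- ifelse(is_snv, NA_real_, 0.001)

  cols <- c(variant_core_cols(), predictor_tools())
  v <- v[, cols]
  attr(v, "predictor_cols") <- predictor_tools()
  list(variants = v, clinical = clinical)
}
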
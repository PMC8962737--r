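#' Configuration of the four-criterion deleteriousness filter
#'
#' Defaults encode the filter as printed in its source conventions: read
#' depth strictly greater than 10; only non-synonymous exonic classes
#' (nonsynonymous SNV, frameshift indel, non-frameshift indel, stopgain,
#' stoploss); East-Asian population frequency at most 1% (boundary
#' inclusive, and a missing frequency counts as rare); SNV consensus
#' requires damaging votes from more than twelve of the 15 tools
#' (`min_votes = 13`); VEST-Indel deleteriousness requires score >= 0.85
#' and p-value <= 0.01 (both boundaries inclusive); haploinsufficiency
#' rating "3" (sufficient evidence) qualifies truncating variants.
#'
#' @param min_depth_exclusive Depth gate; variants pass only with
#'   `depth > min_depth_exclusive`.
#' @param max_pop_freq Maximum ExAC_EAS allele frequency (inclusive).
#' @param min_votes Minimum damaging votes for the SNV consensus route.
#' @param vest_score_min,vest_p_max VEST-Indel thresholds (inclusive).
#' @param allowed_classes Variant classes admitted by the gate.
#' @param missing_freq_passes Should a missing population frequency pass
#'   the rarity gate (rare-by-absence)?
#' @param hi_accepted Haploinsufficiency rating codes accepted as evidence.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth_exclusive = 10L,
                          max_pop_freq = 0.01,
                          min_votes = 13L,
                          vest_score_min = 0.85,
                          vest_p_max = 0.01,
                          allowed_classes = c("nonsynonymous_SNV",
                                              "frameshift_indel",
                                              "nonframeshift_indel",
                                              "stopgain", "stoploss"),
                          missing_freq_passes = TRUE,
                          hi_accepted = "3") {
  stopifnot(max_pop_freq >= 0, max_pop_freq <= 1,
            min_votes >= 1,
            vest_score_min >= 0, vest_score_min <= 1,
            vest_p_max >= 0, vest_p_max <= 1,
            all(allowed_classes %in% variant_classes()))
  structure(list(min_depth_exclusive = as.integer(min_depth_exclusive),
                 max_pop_freq = max_pop_freq,
                 min_votes = as.integer(min_votes),
                 vest_score_min = vest_score_min,
                 vest_p_max = vest_p_max,
                 allowed_classes = allowed_classes,
                 missing_freq_passes = isTRUE(missing_freq_passes),
                 hi_accepted = as.character(hi_accepted)),
            class = "filter_config")
}

#' Evaluate the depth / class / frequency gate
#'
#' A total function over well-formed variants: a variant passes iff its
#' depth exceeds the depth threshold strictly, its class is admitted, and
#' its population frequency is at most `max_pop_freq` (or missing, when
#' `missing_freq_passes`).
#'
#' @param variants Variant table.
#' @param cfg A [filter_config()].
#' @return `data.frame` with logical `pass` and character `reason`
#'   ("pass", or the first failing criterion:
#'   "depth_le_threshold", "class_not_allowed", "freq_above_max").
#' @export
gate_variant <- function(variants, cfg = filter_config()) {
  depth_ok <- !is.na(variants$depth) &
    variants$depth > cfg$min_depth_exclusive
  class_ok <- !is.na(variants$variant_class) &
    variants$variant_class %in% cfg$allowed_classes
  freq <- variants$exac_eas_freq
  freq_ok <- ifelse(is.na(freq), cfg$missing_freq_passes,
                    freq <= cfg$max_pop_freq)
  reason <- rep("pass", nrow(variants))
  reason[!freq_ok] <- "freq_above_max"
  reason[!class_ok] <- "class_not_allowed"
  reason[!depth_ok] <- "depth_le_threshold"
  data.frame(pass = depth_ok & class_ok & freq_ok, reason = reason,
             stringsAsFactors = FALSE)
}

hi_lookup <- function(genes, hi_table) {
  if (is.null(hi_table) || nrow(hi_table) == 0) {
    return(rep(NA_character_, length(genes)))
  }
  as.character(hi_table$rating)[match(genes, hi_table$gene)]
}

#' Classify variants as deleterious with type-specific routing
#'
#' Variants failing the [gate_variant()] gate are rejected outright. The
#' remainder route by functional class:
#' \describe{
#'   \item{nonsynonymous SNV}{deleterious iff at least `min_votes` of the
#'     15 registered tools vote damaging (`snv_consensus`).}
#'   \item{frameshift indel / stopgain}{deleterious iff the gene's
#'     haploinsufficiency rating is accepted, or the VEST-Indel score and
#'     p-value meet their thresholds (`truncation_haploinsufficiency`).
#'     The two lines of evidence combine by OR: haploinsufficiency is the
#'     primary criterion and VEST-Indel the secondary one, with no
#'     precedence beyond that.}
#'   \item{non-frameshift indel}{deleterious iff the VEST-Indel thresholds
#'     are met (`indel_vest`).}
#'   \item{stoploss}{retained unconditionally once past the gate
#'     (`stoploss_retained`): read-through extends the protein and is
#'     treated as inherently damaging.}
#' }
#' Missing VEST fields on a VEST-only route yield `deleterious = FALSE`
#' with reason `vest_missing`. The `reasons` column records every
#' criterion outcome in evaluation order, so each verdict is auditable.
#'
#' @param variants Variant table.
#' @param cfg A [filter_config()].
#' @param rules Predictor rule registry.
#' @param hi_table Optional `data.frame(gene, rating)` of
#'   haploinsufficiency ratings.
#' @return The variant table with columns `deleterious` (logical), `route`
#'   (one of snv_consensus, indel_vest, truncation_haploinsufficiency,
#'   stoploss_retained, rejected_gate), `votes_damaging` (integer, NA off
#'   the consensus route), and `reasons` (";"-separated audit trail).
#' @export
classify_variants <- function(variants, cfg = filter_config(),
                              rules = default_predictor_rules(),
                              hi_table = NULL) {
  n <- nrow(variants)
  gate <- gate_variant(variants, cfg)
  votes_all <- count_damaging_votes(variants, rules)
  hi <- hi_lookup(variants$gene, hi_table)

  deleterious <- logical(n)
  route <- rep("rejected_gate", n)
  votes_out <- rep(NA_integer_, n)
  reasons <- character(n)

  vest_ok <- !is.na(variants$vest_indel_score) &
    !is.na(variants$vest_indel_p) &
    variants$vest_indel_score >= cfg$vest_score_min &
    variants$vest_indel_p <= cfg$vest_p_max
  vest_missing <- is.na(variants$vest_indel_score) |
    is.na(variants$vest_indel_p)
  hi_ok <- !is.na(hi) & hi %in% cfg$hi_accepted

  for (i in seq_len(n)) {
    if (!gate$pass[i]) {
      reasons[i] <- paste0("gate_fail:", gate$reason[i])
      next
    }
    trail <- "gate_pass"
    cls <- variants$variant_class[i]
    if (cls == "nonsynonymous_SNV") {
      route[i] <- "snv_consensus"
      votes_out[i] <- votes_all[i]
      deleterious[i] <- votes_all[i] >= cfg$min_votes
      trail <- c(trail, sprintf("votes=%d/%d(min=%d)", votes_all[i],
                                length(rules), cfg$min_votes))
    } else if (cls %in% c("frameshift_indel", "stopgain")) {
      route[i] <- "truncation_haploinsufficiency"
      trail <- c(trail,
                 if (hi_ok[i]) "haploinsufficiency_accepted"
                 else if (is.na(hi[i])) "haploinsufficiency_unrated"
                 else "haploinsufficiency_rejected",
                 if (vest_ok[i]) "vest_pass"
                 else if (vest_missing[i]) "vest_missing" else "vest_fail")
      deleterious[i] <- hi_ok[i] || vest_ok[i]
    } else if (cls == "nonframeshift_indel") {
      route[i] <- "indel_vest"
      trail <- c(trail, if (vest_ok[i]) "vest_pass"
                 else if (vest_missing[i]) "vest_missing" else "vest_fail")
      deleterious[i] <- vest_ok[i]
    } else if (cls == "stoploss") {
      route[i] <- "stoploss_retained"
      trail <- c(trail, "stoploss_retained")
      deleterious[i] <- TRUE
    } else {
      # class admitted by a permissive config but with no evidence route
      route[i] <- "rejected_gate"
      trail <- c(trail, "no_evidence_route")
    }
    reasons[i] <- paste(trail, collapse = ";")
  }

  out <- variants
  out$deleterious <- deleterious
  out$route <- route
  out$votes_damaging <- votes_out
  out$reasons <- reasons
  attr(out, "predictor_cols") <- attr(variants, "predictor_cols")
  out
}

#' Count deleterious variants per class and tumor group
#'
#' @param verdicts Verdict table from [classify_variants()].
#' @return `data.frame(variant_class, tumor_group, n)` in fixed class order
#'   covering all class/group combinations (zeros included); the per-group
#'   totals equal the number of deleterious verdicts in that group.
#' @export
summarize_by_class <- function(verdicts) {
  classes <- variant_classes()
  groups <- c("primary", "metastatic")
  grid <- expand.grid(variant_class = classes, tumor_group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(verdicts) == 0 || !"deleterious" %in% names(verdicts)) {
    grid$n <- 0L
    return(grid)
  }
  del <- verdicts[verdicts$deleterious, , drop = FALSE]
  grid$n <- vapply(seq_len(nrow(grid)), function(i) {
    sum(del$variant_class == grid$variant_class[i] &
          del$tumor_group == grid$tumor_group[i], na.rm = TRUE)
  }, integer(1))
  grid
}
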
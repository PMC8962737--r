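# Independent oracles and random-input generators shared across tests.
# These deliberately re-derive every quantity from first principles rather
# than calling the package's own code paths.

# brute-force damaging-vote tally, one rule at a time, one row at a time
naive_votes <- function(variants, rules = default_predictor_rules()) {
  vapply(seq_len(nrow(variants)), function(i) {
    tot <- 0L
    for (r in rules) {
      val <- as.character(variants[[r$tool]][i])
      if (is.na(val) || val %in% c(".", "")) next
      hit <- if (r$mode == "categorical") {
        val %in% r$damaging_categories
      } else {
        s <- suppressWarnings(as.numeric(val))
        if (is.na(s)) FALSE
        else if (identical(r$direction, "le")) s <= r$threshold
        else s >= r$threshold
      }
      tot <- tot + as.integer(isTRUE(hit))
    }
    tot
  }, integer(1))
}

# independent re-evaluation of the full deleteriousness decision
naive_deleterious <- function(variants, cfg = filter_config(),
                              rules = default_predictor_rules(),
                              hi_table = NULL) {
  votes <- naive_votes(variants, rules)
  vapply(seq_len(nrow(variants)), function(i) {
    depth <- variants$depth[i]
    cls <- variants$variant_class[i]
    freq <- variants$exac_eas_freq[i]
    gate <- !is.na(depth) && depth > cfg$min_depth_exclusive &&
      !is.na(cls) && cls %in% cfg$allowed_classes &&
      (if (is.na(freq)) cfg$missing_freq_passes else
        freq <= cfg$max_pop_freq)
    if (!gate) return(FALSE)
    vs <- variants$vest_indel_score[i]
    vp <- variants$vest_indel_p[i]
    vest_ok <- !is.na(vs) && !is.na(vp) &&
      vs >= cfg$vest_score_min && vp <= cfg$vest_p_max
    hi_ok <- FALSE
    if (!is.null(hi_table)) {
      r <- hi_table$rating[hi_table$gene == variants$gene[i]]
      hi_ok <- length(r) > 0 && !is.na(r[1]) && r[1] %in% cfg$hi_accepted
    }
    if (cls == "nonsynonymous_SNV") votes[i] >= cfg$min_votes
    else if (cls %in% c("frameshift_indel", "stopgain")) hi_ok || vest_ok
    else if (cls == "nonframeshift_indel") vest_ok
    else if (cls == "stoploss") TRUE
    else FALSE
  }, logical(1))
}

# random annotated variants exercising every branch: mixed classes, gate
# boundary depths/frequencies, missing and junk predictor calls
random_variants <- function(n) {
  call_pool <- c("D", "T", "B", "N", "A", "H", "M", "P", "L", ".",
                 NA_character_, "0.95", "0.2", "30", "5", "0.8", "0.4")
  start <- sample.int(1e8, n, replace = TRUE)
  v <- data.frame(
    sample_id = sprintf("PT%d%s", sample(1:8, n, replace = TRUE),
                        sample(c("-P", "-M"), n, replace = TRUE)),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    start = start, end = start,
    ref = sample(c("A", "C", "G", "T", "ACGT"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T", "-"), n, replace = TRUE),
    gene = sprintf("G%d", sample(1:30, n, replace = TRUE)),
    variant_class = sample(variant_classes(), n, replace = TRUE),
    depth = sample(c(0:15, 50, 200), n, replace = TRUE),
    exac_eas_freq = sample(c(NA, 0, 0.001, 0.01, 0.02, 0.3), n,
                           replace = TRUE),
    vest_indel_score = sample(c(NA, 0.2, 0.85, 0.95), n, replace = TRUE),
    vest_indel_p = sample(c(NA, 0.001, 0.01, 0.5), n, replace = TRUE),
    aa_change = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  p <- parse_sample_id(v$sample_id)
  v$patient_id <- p$patient_id
  v$tumor_group <- p$tumor_group
  for (tool in predictor_tools()) {
    v[[tool]] <- sample(call_pool, n, replace = TRUE)
  }
  v
}

random_hi_table <- function(genes) {
  data.frame(gene = genes,
             rating = sample(c("0", "1", "2", "3", "30", NA),
                             length(genes), replace = TRUE),
             stringsAsFactors = FALSE)
}
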
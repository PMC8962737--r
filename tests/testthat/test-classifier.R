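make_variant <- function(variant_class = "nonsynonymous_SNV", depth = 50L,
                         exac_eas_freq = NA_real_, gene = "GENE1",
                         vest_indel_score = NA_real_,
                         vest_indel_p = NA_real_, n_damaging = 0) {
  v <- data.frame(
    sample_id = "S1-P", patient_id = "S1", tumor_group = "primary",
    chrom = "1", start = 100L, end = 100L, ref = "C", alt = "T",
    gene = gene, variant_class = variant_class, depth = depth,
    exac_eas_freq = exac_eas_freq, vest_indel_score = vest_indel_score,
    vest_indel_p = vest_indel_p, aa_change = NA_character_,
    stringsAsFactors = FALSE
  )
  rules <- default_predictor_rules()
  tools <- predictor_tools()
  for (k in seq_along(tools)) {
    r <- rules[[tools[k]]]
    v[[tools[k]]] <- if (k <= n_damaging) {
      if (r$mode == "categorical") r$damaging_categories[1]
      else as.character(r$threshold + 1)
    } else {
      if (r$mode == "categorical") "T" else as.character(r$threshold / 2)
    }
  }
  v
}

test_that("gate applies strict depth, inclusive frequency, class filter", {
  cfg <- filter_config()
  expect_false(gate_variant(make_variant(depth = 10L), cfg)$pass)
  expect_equal(gate_variant(make_variant(depth = 10L), cfg)$reason,
               "depth_le_threshold")
  expect_true(gate_variant(make_variant(depth = 11L,
                                        exac_eas_freq = 0.01), cfg)$pass)
  expect_false(gate_variant(make_variant(exac_eas_freq = 0.0101),
                            cfg)$pass)
  expect_false(gate_variant(make_variant("synonymous_SNV"), cfg)$pass)
  expect_equal(gate_variant(make_variant("synonymous_SNV"), cfg)$reason,
               "class_not_allowed")
  # missing frequency passes by default, fails when switched off
  expect_true(gate_variant(make_variant(), cfg)$pass)
  strict <- filter_config(missing_freq_passes = FALSE)
  expect_false(gate_variant(make_variant(), strict)$pass)
})

test_that("vote counting saturates, handles missing, matches brute force", {
  expect_equal(count_damaging_votes(make_variant(n_damaging = 15)), 15L)
  all_missing <- make_variant()
  for (tool in predictor_tools()) all_missing[[tool]] <- NA_character_
  expect_equal(count_damaging_votes(all_missing), 0L)

  # exactly SIFT, MetaSVM damaging calls plus a high CADD score
  v3 <- make_variant()
  v3$SIFT <- "D"; v3$MetaSVM <- "D"; v3$CADD <- "35"
  expect_equal(count_damaging_votes(v3), 3L)
  expect_equal(naive_votes(v3), 3L)

  set.seed(7)
  rv <- random_variants(400)
  expect_equal(count_damaging_votes(rv), naive_votes(rv))
})

test_that("unregistered predictor columns warn and are ignored", {
  v <- make_variant(n_damaging = 15)
  v$SomeNewTool <- "D"
  attr(v, "predictor_cols") <- c(predictor_tools(), "SomeNewTool")
  expect_warning(votes <- count_damaging_votes(v), "SomeNewTool")
  expect_equal(votes, 15L)
})

test_that("classification routes by variant class", {
  cfg <- filter_config()
  # SNV consensus: >12 of 15 tools
  v <- classify_variants(make_variant(n_damaging = 13), cfg)
  expect_true(v$deleterious)
  expect_equal(v$route, "snv_consensus")
  expect_equal(v$votes_damaging, 13L)
  expect_false(classify_variants(make_variant(n_damaging = 12),
                                 cfg)$deleterious)

  # VEST-Indel boundaries are inclusive
  nfs <- make_variant("nonframeshift_indel", vest_indel_score = 0.85,
                      vest_indel_p = 0.01)
  expect_true(classify_variants(nfs, cfg)$deleterious)
  expect_equal(classify_variants(nfs, cfg)$route, "indel_vest")
  nfs$vest_indel_score <- 0.8499
  expect_false(classify_variants(nfs, cfg)$deleterious)

  # stoploss retained unconditionally post-gate
  sl <- classify_variants(make_variant("stoploss"), cfg)
  expect_true(sl$deleterious)
  expect_equal(sl$route, "stoploss_retained")
  expect_true(is.na(sl$votes_damaging))
  expect_false(classify_variants(make_variant("stoploss", depth = 5L),
                                 cfg)$deleterious)

  # missing VEST fields on a VEST-only route reject with a reason
  nv <- classify_variants(make_variant("nonframeshift_indel"), cfg)
  expect_false(nv$deleterious)
  expect_match(nv$reasons, "vest_missing")
})

test_that("truncating variants qualify by haploinsufficiency OR VEST", {
  cfg <- filter_config()
  hi <- data.frame(gene = c("GENE1", "GENE2"), rating = c("3", "1"),
                   stringsAsFactors = FALSE)
  fs <- make_variant("frameshift_indel", vest_indel_score = 0.2,
                     vest_indel_p = 0.9)
  # rated 3 -> accepted despite failing VEST
  expect_true(classify_variants(fs, cfg, hi_table = hi)$deleterious)
  # rated 1 -> rejected unless VEST rescues
  fs$gene <- "GENE2"
  expect_false(classify_variants(fs, cfg, hi_table = hi)$deleterious)
  fs$vest_indel_score <- 0.9; fs$vest_indel_p <- 0.001
  expect_true(classify_variants(fs, cfg, hi_table = hi)$deleterious)
  # unrated gene, no hi table at all -> VEST only
  fs$gene <- "GENE9"
  expect_true(classify_variants(fs, cfg)$deleterious)
  v <- classify_variants(fs, cfg, hi_table = hi)
  expect_match(v$reasons, "haploinsufficiency_unrated")
  expect_equal(v$route, "truncation_haploinsufficiency")
})

test_that("classify agrees with an independent naive reimplementation", {
  set.seed(11)
  rv <- random_variants(500)
  hi <- random_hi_table(unique(rv$gene))
  got <- classify_variants(rv, hi_table = hi)
  expect_equal(got$deleterious, naive_deleterious(rv, hi_table = hi))
  # and under a non-default configuration
  cfg2 <- filter_config(min_votes = 10, max_pop_freq = 0.001,
                        min_depth_exclusive = 14,
                        missing_freq_passes = FALSE)
  got2 <- classify_variants(rv, cfg2, hi_table = hi)
  expect_equal(got2$deleterious,
               naive_deleterious(rv, cfg2, hi_table = hi))
})

test_that("every variant gets exactly one route and verdicts are auditable", {
  set.seed(13)
  rv <- random_variants(300)
  v <- classify_variants(rv)
  expect_true(all(v$route %in% c("snv_consensus", "indel_vest",
                                 "truncation_haploinsufficiency",
                                 "stoploss_retained", "rejected_gate")))
  expect_equal(!is.na(v$votes_damaging), v$route == "snv_consensus")
  expect_false(any(v$deleterious & v$route == "rejected_gate"))
  # deleterious implies all gates passed, readable from the reason trail
  expect_true(all(grepl("^gate_pass", v$reasons[v$deleterious])))
})

test_that("stricter thresholds never enlarge the deleterious set", {
  set.seed(17)
  rv <- random_variants(400)
  base <- classify_variants(rv)$deleterious
  stricter <- list(
    filter_config(min_votes = 14),
    filter_config(max_pop_freq = 0.001),
    filter_config(min_depth_exclusive = 30),
    filter_config(min_votes = 15, max_pop_freq = 0.005,
                  min_depth_exclusive = 20)
  )
  for (cfg in stricter) {
    del <- classify_variants(rv, cfg)$deleterious
    expect_true(all(base | !del))
  }
})

test_that("class summary conserves totals and orders deterministically", {
  expect_true(all(summarize_by_class(
    classify_variants(random_variants(0)))$n == 0))

  verdicts <- classify_variants(rbind(
    make_variant(n_damaging = 15), make_variant(n_damaging = 14),
    make_variant("stoploss"), make_variant(n_damaging = 2),
    make_variant("synonymous_SNV"), make_variant(depth = 3L)
  ))
  s <- summarize_by_class(verdicts)
  expect_equal(sum(s$n), 3)
  expect_equal(s$n[s$variant_class == "nonsynonymous_SNV" &
                     s$tumor_group == "primary"], 2L)
  expect_equal(s$n[s$variant_class == "stoploss" &
                     s$tumor_group == "primary"], 1L)

  set.seed(19)
  rv <- random_variants(300)
  v <- classify_variants(rv)
  s2 <- summarize_by_class(v)
  for (grp in c("primary", "metastatic")) {
    expect_equal(sum(s2$n[s2$tumor_group == grp]),
                 sum(v$deleterious & v$tumor_group == grp))
  }
})
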
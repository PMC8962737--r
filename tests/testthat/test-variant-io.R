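ex_variants_path <- system.file("extdata", "example_flna_variants.tsv",
                                package = "metdriver")
ex_clinical_path <- system.file("extdata", "example_clinical.tsv",
                                package = "metdriver")

test_that("bundled variant table parses with sample-suffix conventions", {
  v <- read_variant_table(ex_variants_path)
  expect_equal(nrow(v), 10)
  expect_setequal(unique(v$gene), "FLNA")
  p1m <- v[v$sample_id == "Patient1-M" & v$start == 154360534, ]
  expect_equal(p1m$tumor_group, "metastatic")
  expect_equal(p1m$variant_class, "frameshift_indel")
  expect_equal(p1m$alt, "-")
  expect_equal(p1m$patient_id, "Patient1")
  expect_true(all(v$start <= v$end))
})

test_that("dash glyphs, dots and empty cells normalize to canonical form", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tchrom\tstart\tend\tref\talt\tgene\tvariant_class\tdepth\texac_eas_freq",
    "S1-P\t1\t100\t105\tTGTCAT\t–\tGENE1\tNon-frameshift deletion\t50\t.",
    "S2-M\t1\t200\t200\tC\tT\tGENE2\tnonsynonymous SNV\t.\t0.02",
    "S3-P\t1\t300\t300\tG\tA\tGENE3\tweird stuff\t12\t"
  ), tmp)
  v <- read_variant_table(tmp)
  expect_equal(v$alt[1], "-")
  expect_equal(v$variant_class[1], "nonframeshift_indel")
  expect_true(is.na(v$exac_eas_freq[1]))   # "." is missing, not zero
  expect_true(is.na(v$depth[2]))           # unparseable numeric -> missing
  expect_equal(v$exac_eas_freq[2], 0.02)
  expect_equal(v$variant_class[3], "other")
  expect_true(is.na(v$exac_eas_freq[3]))
})

test_that("header-only file gives an empty table; missing columns error", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tchrom\tstart\tend\tref\talt\tgene\tvariant_class",
             tmp)
  expect_equal(nrow(read_variant_table(tmp)), 0)

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tstart", "S1-P\t1\t100"), tmp2)
  expect_error(read_variant_table(tmp2), "gene")
})

test_that("duplicated variant rows warn and keep the first occurrence", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tchrom\tstart\tend\tref\talt\tgene\tvariant_class\tdepth",
    "S1-P\t1\t100\t100\tC\tT\tGENE1\tnonsynonymous SNV\t40",
    "S1-P\t1\t100\t100\tC\tT\tGENE1\tnonsynonymous SNV\t99"
  ), tmp)
  expect_warning(v <- read_variant_table(tmp), "duplicated")
  expect_equal(nrow(v), 1)
  expect_equal(v$depth, 40L)
})

test_that("an explicit tumor_group column overrides the suffix", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\ttumor_group\tchrom\tstart\tend\tref\talt\tgene\tvariant_class",
    "S1-P\tmetastatic\t1\t100\t100\tC\tT\tGENE1\tnonsynonymous SNV"
  ), tmp)
  v <- read_variant_table(tmp)
  expect_equal(v$tumor_group, "metastatic")
})

test_that("ANNOVAR-style headers map through the annovar_multianno dialect", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("Sample", "Chr", "Start", "End", "Ref", "Alt", "Gene.refGene",
          "ExonicFunc.refGene", "ExAC_EAS", "Depth", "SIFT_pred",
          "CADD_phred", sep = "\t"),
    paste("S1-P", "X", "1000", "1000", "C", "T", "FLNA",
          "nonsynonymous SNV", ".", "55", "D", "33.5", sep = "\t")
  ), tmp)
  v <- read_variant_table(tmp, dialect = "annovar_multianno")
  expect_equal(v$gene, "FLNA")
  expect_equal(v$variant_class, "nonsynonymous_SNV")
  expect_equal(v$depth, 55L)
  expect_true(is.na(v$exac_eas_freq))
  expect_equal(v$SIFT, "D")
  expect_equal(v$CADD, "33.5")
  expect_setequal(attr(v, "predictor_cols"), c("SIFT", "CADD"))
})

test_that("write/read round trip preserves all non-missing fields", {
  set.seed(41)
  for (rep in 1:5) {
    v <- random_variants(30)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    write_variant_table(v, tmp)
    v2 <- read_variant_table(tmp)
    for (col in c("sample_id", "patient_id", "tumor_group", "chrom",
                  "start", "end", "gene", "variant_class", "depth",
                  "exac_eas_freq", "vest_indel_score", "vest_indel_p")) {
      expect_equal(v2[[col]], v[[col]], info = col)
    }
    # injected "." calls come back as missing, never as a number
    for (tool in predictor_tools()) {
      was_dot <- !is.na(v[[tool]]) & v[[tool]] == "."
      expect_true(all(is.na(v2[[tool]][was_dot])))
      kept <- !is.na(v[[tool]]) & v[[tool]] != "."
      expect_equal(v2[[tool]][kept], v[[tool]][kept])
    }
  }
})

test_that("clinical table parses ratings, N.A. values and DFS months", {
  cl <- read_clinical_table(ex_clinical_path)
  expect_equal(nrow(cl), 9)
  expect_equal(cl$dfs_months[cl$patient_id == "Patient9"], 5)
  expect_equal(cl$dfs_months,
               c(62, 80, 28, 72, 22, 38, 42, 24, 5))
  expect_true(is.na(cl$age[cl$patient_id == "Patient6"]))
  expect_true(all(cl$event))
})

test_that("clinical edge cases: header-only, negative DFS, duplicate ids", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("patient_id\tage\tdfs_months", tmp)
  expect_equal(nrow(read_clinical_table(tmp)), 0)

  writeLines(c("patient_id\tdfs_months", "P1\t-3"), tmp)
  expect_error(read_clinical_table(tmp), "negative")

  writeLines(c("patient_id\tdfs_months", "P1\t3", "P1\t5"), tmp)
  expect_error(read_clinical_table(tmp), "duplicated")
})

test_that("report bundle is deterministic and summarizes the worked example", {
  ex <- example_cohort()
  verdicts <- classify_variants(ex$variants)
  rec <- call_susceptible(tally_gene_patients(verdicts))
  strata <- stratify_by_mutation(ex$clinical, verdicts, "FLNA", "primary")
  surv <- list(FLNA = wilcoxon_rank_sum(strata$mutant, strata$wildtype))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(verdicts, rec, surv, d1)
  write_report(verdicts, rec, surv, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
  js <- jsonlite::read_json(file.path(d1, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$n_deleterious, 10)
  expect_equal(js$susceptible_genes, "FLNA")
  expect_equal(js$survival$mean_mutant, 56.0)
  expect_equal(js$survival$mean_wildtype, 23.25)

  # empty input: all counts zero
  d3 <- withr::local_tempdir()
  write_report(verdicts[0, ], NULL, NULL, d3)
  js0 <- jsonlite::read_json(file.path(d3, "summary.json"),
                             simplifyVector = TRUE)
  expect_equal(js0$n_deleterious, 0)
  expect_true(all(js0$deleterious_by_class$n == 0))
})
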
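#' Configuration for the synthetic matched-pair cohort generator
#'
#' The generator emulates the statistical structure of an annotated somatic
#' variant table from a matched primary/metastatic WES cohort: per-patient
#' paired "-P"/"-M" samples, class-conditional predictor calls, VEST-Indel
#' scores from class-conditional Beta distributions, negative-binomial read
#' depths, occasional common-population-frequency variants, and exponential
#' relapse times whose hazard is multiplied by `driver_hazard_ratio` for
#' driver-mutant patients.
#'
#' @param n_patients Number of patients (each contributes a primary and a
#'   metastatic sample).
#' @param driver_genes Gene symbols planted as drivers.
#' @param passenger_genes Gene pool for background (benign) variants.
#' @param driver_mutation_prob Probability a patient carries the driver
#'   mutation (in both samples of the pair).
#' @param n_driver_patients Optional exact number of driver-mutant patients;
#'   overrides `driver_mutation_prob` when supplied.
#' @param passenger_rate Mean number of passenger variants per sample
#'   (Poisson).
#' @param p_damaging_given_deleterious,p_damaging_given_benign Per-tool
#'   probability of a damaging call conditional on the variant's true
#'   class; tools are conditionally independent given the class.
#' @param depth_mu,depth_size Negative-binomial read-depth parameters
#'   (mean 80, dispersion 5 by default, so a small fraction falls at or
#'   below the depth gate).
#' @param freq_spike_prob Fraction of benign variants given a common
#'   ExAC_EAS frequency (the rest are rare or unobserved).
#' @param baseline_hazard Exponential relapse hazard per month for
#'   driver-wild-type patients.
#' @param driver_hazard_ratio Hazard multiplier for driver-mutant patients
#'   (< 1 means the driver mutation extends relapse-free time).
#' @param censoring_rate Expected fraction of censored patients
#'   (independent exponential censoring).
#' @param seed Mandatory integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 20L,
                              driver_genes = "DRV1",
                              passenger_genes = sprintf("PSG%02d", 1:40),
                              driver_mutation_prob = 0.5,
                              n_driver_patients = NULL,
                              passenger_rate = 30,
                              p_damaging_given_deleterious = 0.95,
                              p_damaging_given_benign = 0.10,
                              depth_mu = 80, depth_size = 5,
                              freq_spike_prob = 0.10,
                              baseline_hazard = 0.02,
                              driver_hazard_ratio = 0.4,
                              censoring_rate = 0.10,
                              seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_patients >= 2,
            driver_mutation_prob >= 0, driver_mutation_prob <= 1,
            p_damaging_given_deleterious >= 0,
            p_damaging_given_deleterious <= 1,
            p_damaging_given_benign >= 0, p_damaging_given_benign <= 1,
            freq_spike_prob >= 0, freq_spike_prob <= 1,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0, driver_hazard_ratio > 0)
  structure(as.list(environment()), class = "simulation_config")
}

# one damaging / one benign raw call per registered tool
damaging_call_for <- function(rule) {
  if (rule$mode == "categorical") rule$damaging_categories[1]
  else as.character(signif(rule$threshold * 1.5, 6))
}
benign_call_for <- function(rule) {
  if (rule$mode == "categorical") {
    switch(rule$tool,
           SIFT = "T", Polyphen2_HDIV = "B", Polyphen2_HVAR = "B",
           LRT = "N", MutationTaster = "N", MutationAssessor = "N",
           FATHMM = "T", PROVEAN = "N", MetaSVM = "T", MetaLR = "T",
           M_CAP = "T", FATHMM_MKL = "N", "T")
  } else as.character(signif(rule$threshold * 0.5, 6))
}

#' Simulate class-conditional predictor calls
#'
#' Draws, for each of `n` variants, the 15 registered tool calls: each tool
#' independently votes damaging with probability `p_damaging` and benign
#' otherwise, with a raw call string matching the tool's convention.
#'
#' @param n Number of variants.
#' @param p_damaging Per-tool damaging probability.
#' @param rules Predictor rule registry.
#' @return `data.frame` with one character column per tool.
#' @export
simulate_predictor_calls <- function(n, p_damaging,
                                     rules = default_predictor_rules()) {
  out <- data.frame(matrix(NA_character_, nrow = n, ncol = length(rules)),
                    stringsAsFactors = FALSE)
  names(out) <- names(rules)
  for (tool in names(rules)) {
    dmg <- stats::runif(n) < p_damaging
    out[[tool]] <- ifelse(dmg, damaging_call_for(rules[[tool]]),
                          benign_call_for(rules[[tool]]))
  }
  out
}

sim_variant_rows <- function(sample_id, patient_id, tumor_group, genes,
                             true_class, cfg) {
  n <- length(genes)
  if (n == 0) return(NULL)
  is_del <- true_class == "deleterious"
  # drivers are mostly missense, with some truncating events
  class_probs_del <- c(nonsynonymous_SNV = 0.70, frameshift_indel = 0.10,
                       nonframeshift_indel = 0.05, stopgain = 0.10,
                       stoploss = 0.05)
  class_probs_ben <- c(nonsynonymous_SNV = 0.80, frameshift_indel = 0.05,
                       nonframeshift_indel = 0.05, stopgain = 0.02,
                       stoploss = 0.0, synonymous_SNV = 0.08)
  vclass <- character(n)
  for (i in seq_len(n)) {
    p <- if (is_del[i]) class_probs_del else class_probs_ben
    vclass[i] <- sample(names(p), 1, prob = p)
  }

  start <- sample.int(2e8, n, replace = TRUE)
  depth <- stats::rnbinom(n, mu = cfg$depth_mu, size = cfg$depth_size)

  freq <- rep(NA_real_, n)
  common <- !is_del & stats::runif(n) < cfg$freq_spike_prob
  freq[common] <- stats::runif(sum(common), 0.05, 0.5)
  rare_obs <- !common & stats::runif(n) < 0.5
  freq[rare_obs] <- stats::runif(sum(rare_obs), 0, 0.005)

  calls <- matrix(NA_character_, nrow = n,
                  ncol = length(predictor_tools()),
                  dimnames = list(NULL, predictor_tools()))
  is_snv <- vclass %in% c("nonsynonymous_SNV", "synonymous_SNV")
  if (any(is_snv)) {
    p_dmg <- ifelse(is_del[is_snv], cfg$p_damaging_given_deleterious,
                    cfg$p_damaging_given_benign)
    rules <- default_predictor_rules()
    for (tool in names(rules)) {
      dmg <- stats::runif(sum(is_snv)) < p_dmg
      calls[is_snv, tool] <- ifelse(dmg, damaging_call_for(rules[[tool]]),
                                    benign_call_for(rules[[tool]]))
    }
  }

  vest_s <- rep(NA_real_, n)
  vest_p <- rep(NA_real_, n)
  is_indel <- vclass %in% c("frameshift_indel", "nonframeshift_indel",
                            "stopgain")
  if (any(is_indel)) {
    k <- sum(is_indel)
    del_i <- is_del[is_indel]
    vest_s[is_indel] <- ifelse(del_i, stats::rbeta(k, 9, 1),
                               stats::rbeta(k, 2, 8))
    vest_p[is_indel] <- ifelse(del_i, stats::rbeta(k, 1, 50),
                               stats::runif(k))
  }

  snv_like <- vclass %in% c("nonsynonymous_SNV", "synonymous_SNV",
                            "stopgain", "stoploss")
  ref <- ifelse(snv_like, sample(c("A", "C", "G", "T"), n, replace = TRUE),
                "ACGT")
  alt <- ifelse(snv_like, sample(c("A", "C", "G", "T"), n, replace = TRUE),
                "-")

  out <- data.frame(
    sample_id = sample_id, patient_id = patient_id,
    tumor_group = tumor_group,
    chrom = sample(c(as.character(1:22), "X"), n, replace = TRUE),
    start = start, end = start + ifelse(snv_like, 0L, 3L),
    ref = ref, alt = alt, gene = genes, variant_class = vclass,
    depth = depth, exac_eas_freq = freq,
    vest_indel_score = vest_s, vest_indel_p = vest_p,
    aa_change = NA_character_, stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(calls, stringsAsFactors = FALSE))
}

#' Simulate a matched primary/metastatic cohort with known ground truth
#'
#' Driver-mutant patients carry one truly deleterious variant per driver
#' gene in each of their two samples; every sample additionally receives a
#' Poisson number of benign passenger variants. Relapse (DFS) times are
#' exponential with the driver hazard ratio applied to mutant patients;
#' censoring is independent exponential with rate chosen so the expected
#' censored fraction equals `censoring_rate`.
#'
#' The generator also emits a haploinsufficiency rating table: driver
#' genes carry rating "3" (sufficient evidence of dosage sensitivity, as
#' established driver genes typically do), passenger genes a mix of lower
#' ratings and no rating. Pass it to [classify_variants()] so truncating
#' driver variants route through the haploinsufficiency check.
#'
#' @param cfg A [simulation_config()].
#' @return List with `variants` (canonical variant table), `clinical`
#'   (clinical table), `hi_table` (`data.frame(gene, rating)`), and
#'   `truth` (list with per-patient `driver_status` and per-variant
#'   `variant_truth` containing `true_class`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  patients <- sprintf("SP%03d", seq_len(cfg$n_patients))

  hi_table <- data.frame(
    gene = c(cfg$driver_genes, cfg$passenger_genes),
    rating = c(rep("3", length(cfg$driver_genes)),
               sample(c("0", "1", "2", NA), length(cfg$passenger_genes),
                      replace = TRUE)),
    stringsAsFactors = FALSE
  )

  if (!is.null(cfg$n_driver_patients)) {
    stopifnot(cfg$n_driver_patients <= cfg$n_patients)
    driver <- logical(cfg$n_patients)
    driver[sample.int(cfg$n_patients, cfg$n_driver_patients)] <- TRUE
  } else {
    driver <- stats::runif(cfg$n_patients) < cfg$driver_mutation_prob
  }

  rows <- list()
  truth_class <- list()
  for (i in seq_along(patients)) {
    for (grp in c("primary", "metastatic")) {
      sid <- paste0(patients[i], if (grp == "primary") "-P" else "-M")
      genes <- character(0); tclass <- character(0)
      if (driver[i]) {
        genes <- c(genes, cfg$driver_genes)
        tclass <- c(tclass, rep("deleterious", length(cfg$driver_genes)))
      }
      n_psg <- stats::rpois(1, cfg$passenger_rate)
      if (n_psg > 0) {
        genes <- c(genes, sample(cfg$passenger_genes, n_psg,
                                 replace = TRUE))
        tclass <- c(tclass, rep("benign", n_psg))
      }
      if (length(genes) == 0) next
      rows[[length(rows) + 1L]] <-
        sim_variant_rows(sid, patients[i], grp, genes, tclass, cfg)
      truth_class[[length(truth_class) + 1L]] <- tclass
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  attr(variants, "predictor_cols") <- predictor_tools()

  hazard <- cfg$baseline_hazard *
    ifelse(driver, cfg$driver_hazard_ratio, 1)
  event_time <- stats::rexp(cfg$n_patients, rate = hazard)
  if (cfg$censoring_rate > 0) {
    cens_rate <- hazard * cfg$censoring_rate / (1 - cfg$censoring_rate)
    cens_time <- stats::rexp(cfg$n_patients, rate = cens_rate)
  } else {
    cens_time <- rep(Inf, cfg$n_patients)
  }
  clinical <- data.frame(
    patient_id = patients,
    age = round(stats::rnorm(cfg$n_patients, 52, 10)),
    tnm = NA_character_, er = NA_character_, pr = NA_character_,
    her2 = NA_character_,
    dfs_months = pmin(event_time, cens_time),
    event = event_time <= cens_time,
    stringsAsFactors = FALSE
  )

  truth <- list(
    driver_status = data.frame(patient_id = patients,
                               driver_mutant = driver,
                               stringsAsFactors = FALSE),
    variant_truth = data.frame(
      sample_id = variants$sample_id, gene = variants$gene,
      start = variants$start,
      true_class = unlist(truth_class),
      stringsAsFactors = FALSE)
  )
  list(variants = variants, clinical = clinical, hi_table = hi_table,
       truth = truth)
}

#' Simulate a two-arm survival cohort
#'
#' Arm B's hazard is `baseline_hazard * hazard_ratio`; censoring as in
#' [simulate_cohort()]. Used to exercise the Kaplan-Meier estimator and
#' log-rank test under a known generating model.
#'
#' @param n_per_arm Patients per arm.
#' @param baseline_hazard Arm A exponential hazard per month.
#' @param hazard_ratio Arm B hazard multiplier.
#' @param censoring_rate Expected censored fraction.
#' @return `data.frame(arm, time, event)`.
#' @export
simulate_survival_arms <- function(n_per_arm, baseline_hazard = 0.02,
                                   hazard_ratio = 1, censoring_rate = 0) {
  arm <- rep(c("A", "B"), each = n_per_arm)
  rate <- ifelse(arm == "A", baseline_hazard,
                 baseline_hazard * hazard_ratio)
  event_time <- stats::rexp(2 * n_per_arm, rate)
  if (censoring_rate > 0) {
    cens <- stats::rexp(2 * n_per_arm,
                        rate * censoring_rate / (1 - censoring_rate))
  } else {
    cens <- rep(Inf, 2 * n_per_arm)
  }
  data.frame(arm = arm, time = pmin(event_time, cens),
             event = event_time <= cens, stringsAsFactors = FALSE)
}
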
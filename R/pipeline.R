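read_hi_table <- function(path) {
  raw <- read_delim_guess(path)
  names(raw) <- tolower(names(raw))
  if (!all(c("gene", "rating") %in% names(raw))) {
    stop("haploinsufficiency table needs columns: gene, rating")
  }
  data.frame(gene = raw$gene, rating = normalize_missing(raw$rating),
             stringsAsFactors = FALSE)
}

config_digest <- function(config) {
  # canonical JSON of the sorted config; stable across sessions
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}

validate_pipeline_config <- function(config) {
  known <- c("seed", "output_dir", "inputs", "filter", "recurrence",
             "survival")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  inp <- config$inputs
  if (is.null(inp) || (is.null(inp$simulate) &&
                       (is.null(inp$variants) || is.null(inp$clinical)))) {
    stop("config error: inputs must provide either 'simulate' parameters ",
         "or both 'variants' and 'clinical' paths")
  }
  invisible(config)
}

#' Run the full prioritization pipeline from a configuration
#'
#' Executes read (or simulate) -> gate/classify -> class summary ->
#' recurrence -> mutation-stratified survival -> report, writing TSV audit
#' tables, a JSON summary, and a run manifest to the output directory.
#' Output is deterministic for a fixed configuration and inputs (manifest
#' timestamps aside).
#'
#' Config keys (YAML file or named list): `seed`; `output_dir`;
#' `inputs` (`variants`, `clinical`, `dialect`, `hi_table`, or `simulate`
#' with [simulation_config()] parameters); `filter` ([filter_config()]
#' parameters); `recurrence` (`min_patients`, `mode`); `survival`
#' (`genes` — explicit symbols or "susceptible" —, `group`,
#' `exact_limit`).
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list.
#' @return List with `verdicts`, `class_summary`, `recurrence`,
#'   `survival`, `manifest`, and the output `files`; invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  seed <- config$seed

  # --- inputs --------------------------------------------------------
  inp <- config$inputs
  input_digests <- character(0)
  sim_hi <- NULL
  if (!is.null(inp$simulate)) {
    sim_args <- inp$simulate
    if (!is.null(seed) && is.null(sim_args$seed)) sim_args$seed <- seed
    cohort <- do.call(simulation_config, sim_args)
    sim <- simulate_cohort(cohort)
    variants <- sim$variants
    clinical <- sim$clinical
    sim_hi <- sim$hi_table
  } else {
    variants <- read_variant_table(
      inp$variants, dialect = inp$dialect %||% "generic_tsv",
      column_map = unlist(inp$column_map))
    clinical <- read_clinical_table(inp$clinical)
    input_digests <- tools::md5sum(c(inp$variants, inp$clinical))
  }
  hi_table <- if (!is.null(inp$hi_table)) read_hi_table(inp$hi_table)
  else sim_hi

  # --- classify ------------------------------------------------------
  cfg <- do.call(filter_config, config$filter %||% list())
  verdicts <- classify_variants(variants, cfg, hi_table = hi_table)
  class_summary <- summarize_by_class(verdicts)
  message(sprintf("classify: %d variants in, %d deleterious",
                  nrow(verdicts), sum(verdicts$deleterious)))

  # --- recurrence ----------------------------------------------------
  rec_cfg <- config$recurrence %||% list()
  tallies <- tally_gene_patients(verdicts)
  recurrence <- call_susceptible(tallies,
                                 min_patients = rec_cfg$min_patients %||% 2L,
                                 mode = rec_cfg$mode %||% "shared")
  message(sprintf("recurrence: %d susceptible gene(s)", nrow(recurrence)))

  # --- survival ------------------------------------------------------
  surv_cfg <- config$survival %||% list()
  genes <- surv_cfg$genes %||% "susceptible"
  if (identical(genes, "susceptible")) genes <- recurrence$gene
  group <- surv_cfg$group %||% "primary"
  survival <- list()
  for (g in genes) {
    strata <- stratify_by_mutation(clinical, verdicts, g, group)
    if (length(strata$mutant) == 0 || length(strata$wildtype) == 0) {
      message("survival: skipping ", g, " (degenerate stratification)")
      next
    }
    survival[[g]] <- wilcoxon_rank_sum(
      strata$mutant, strata$wildtype,
      exact_limit = surv_cfg$exact_limit %||% 12L)
  }

  # --- report + manifest --------------------------------------------
  files <- character(0)
  manifest <- list(
    tool = "metdriver",
    version = as.character(utils::packageVersion("metdriver")),
    config_hash = config_digest(config[setdiff(names(config),
                                               "output_dir")]),
    input_digests = as.list(input_digests),
    seed = seed %||% NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(config$output_dir)) {
    files <- write_report(verdicts, recurrence, survival,
                          config$output_dir)
    mpath <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, mpath)
  }
  invisible(list(verdicts = verdicts, class_summary = class_summary,
                 recurrence = recurrence, survival = survival,
                 manifest = manifest, files = files))
}
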
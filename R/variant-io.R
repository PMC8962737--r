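#' Recognized functional variant classes
#'
#' @return Character vector of canonical class labels.
#' @export
variant_classes <- function() {
  c("nonsynonymous_SNV", "synonymous_SNV", "frameshift_indel",
    "nonframeshift_indel", "stopgain", "stoploss", "other")
}

# canonical non-predictor columns of a variant table
variant_core_cols <- function() {
  c("sample_id", "patient_id", "tumor_group", "chrom", "start", "end",
    "ref", "alt", "gene", "variant_class", "depth", "exac_eas_freq",
    "vest_indel_score", "vest_indel_p", "aa_change")
}

normalize_missing <- function(x) {
  x <- as.character(x)
  x[x %in% c(".", "", "NA", "N.A.", "N.A")] <- NA_character_
  x
}

as_num <- function(x) suppressWarnings(as.numeric(normalize_missing(x)))
as_int <- function(x) suppressWarnings(as.integer(round(as_num(x))))

# both ASCII hyphen and en/em dash mark an absent allele
normalize_allele <- function(x) {
  x <- normalize_missing(x)
  x[x %in% c("-", "–", "—")] <- "-"
  toupper(x)
}

#' Map free-text functional annotations to canonical variant classes
#'
#' Accepts both canonical labels and ANNOVAR-style exonic function strings
#' ("nonsynonymous SNV", "frameshift deletion", "Non-frameshift insertion",
#' "stopgain", ...). Unrecognized values map to "other".
#'
#' @param x Character vector of functional annotations.
#' @return Character vector of values from [variant_classes()].
#' @export
normalize_variant_class <- function(x) {
  key <- tolower(gsub("[ _-]+", "", normalize_missing(x)))
  out <- rep("other", length(key))
  out[key %in% c("nonsynonymoussnv", "missense")] <- "nonsynonymous_SNV"
  out[key %in% c("synonymoussnv", "synonymous")] <- "synonymous_SNV"
  out[key %in% c("frameshiftindel", "frameshiftdeletion",
                 "frameshiftinsertion", "frameshiftsubstitution")] <-
    "frameshift_indel"
  out[key %in% c("nonframeshiftindel", "nonframeshiftdeletion",
                 "nonframeshiftinsertion", "nonframeshiftsubstitution")] <-
    "nonframeshift_indel"
  out[key %in% "stopgain"] <- "stopgain"
  out[key %in% "stoploss"] <- "stoploss"
  out[is.na(key)] <- NA_character_
  out
}

#' Derive tumor group and patient id from sample labels
#'
#' Matched-pair cohorts label samples `<patient>-P` (primary tumor) and
#' `<patient>-M` (metastatic tumor). An explicit `tumor_group` /
#' `patient_id` column in the input overrides this convention.
#'
#' @param sample_id Character vector of sample labels.
#' @return List with `tumor_group` ("primary"/"metastatic"/NA) and
#'   `patient_id` (suffix stripped where present).
#' @export
parse_sample_id <- function(sample_id) {
  sample_id <- as.character(sample_id)
  group <- rep(NA_character_, length(sample_id))
  group[grepl("-P$", sample_id, ignore.case = TRUE)] <- "primary"
  group[grepl("-M$", sample_id, ignore.case = TRUE)] <- "metastatic"
  patient <- sub("-[PM]$", "", sample_id, ignore.case = TRUE)
  list(tumor_group = group, patient_id = patient)
}

# default file-column -> internal-field map for ANNOVAR multianno output;
# depth and sample come from non-standard columns, hence overridable
annovar_column_map <- function() {
  c(sample_id = "Sample", chrom = "Chr", start = "Start", end = "End",
    ref = "Ref", alt = "Alt", gene = "Gene.refGene",
    variant_class = "ExonicFunc.refGene", aa_change = "AAChange.refGene",
    depth = "Depth", exac_eas_freq = "ExAC_EAS",
    SIFT = "SIFT_pred", Polyphen2_HDIV = "Polyphen2_HDIV_pred",
    Polyphen2_HVAR = "Polyphen2_HVAR_pred", LRT = "LRT_pred",
    MutationTaster = "MutationTaster_pred",
    MutationAssessor = "MutationAssessor_pred", FATHMM = "FATHMM_pred",
    PROVEAN = "PROVEAN_pred", VEST3 = "VEST3_score", MetaSVM = "MetaSVM_pred",
    MetaLR = "MetaLR_pred", M_CAP = "M-CAP_pred", CADD = "CADD_phred",
    FATHMM_MKL = "fathmm-MKL_coding_pred",
    fitCons = "integrated_fitCons_score",
    vest_indel_score = "VEST_indel_score", vest_indel_p = "VEST_indel_pvalue")
}

read_delim_guess <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read an annotated somatic variant table
#'
#' Normalizes a tab- or comma-separated annotation table (one row per
#' somatic variant per sample) into the package's canonical variant table.
#' Coordinates are 1-based inclusive; an absent allele in an indel is "-"
#' (en/em dashes are accepted and normalized); "." and empty cells become
#' missing values, never zeros.
#'
#' @param path Path to the delimited file (TSV or CSV; header required).
#' @param dialect "generic_tsv" for files already using the canonical column
#'   names, or "annovar_multianno" for ANNOVAR-style headers
#'   (`Gene.refGene`, `ExonicFunc.refGene`, `SIFT_pred`, ...).
#' @param column_map Optional named character vector overriding entries of
#'   the dialect's column map (names = internal fields, values = file
#'   columns).
#' @return A `data.frame` with columns `sample_id`, `patient_id`,
#'   `tumor_group`, `chrom`, `start`, `end`, `ref`, `alt`, `gene`,
#'   `variant_class`, `depth`, `exac_eas_freq`, one character column per
#'   registered predictor tool, `vest_indel_score`, `vest_indel_p`,
#'   `aa_change`. The attribute `predictor_cols` records which predictor
#'   columns were present in the file.
#' @export
read_variant_table <- function(path,
                               dialect = c("generic_tsv", "annovar_multianno"),
                               column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant table not found: ", path)
  raw <- read_delim_guess(path)

  map <- if (dialect == "annovar_multianno") annovar_column_map() else {
    stats::setNames(c(variant_core_cols(), predictor_tools()),
                    c(variant_core_cols(), predictor_tools()))
  }
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  pick <- function(field) {
    col <- unname(map[field])
    if (!is.na(col) && col %in% names(raw)) raw[[col]]
    else rep(NA_character_, nrow(raw))
  }

  for (field in c("chrom", "gene", "variant_class")) {
    col <- unname(map[field])
    if (is.na(col) || !col %in% names(raw)) {
      stop("variant table is missing mandatory column '",
           if (is.na(col)) field else col, "' (field: ", field, ")")
    }
  }

  out <- data.frame(
    sample_id = normalize_missing(pick("sample_id")),
    patient_id = normalize_missing(pick("patient_id")),
    tumor_group = normalize_missing(pick("tumor_group")),
    chrom = normalize_missing(pick("chrom")),
    start = as_int(pick("start")),
    end = as_int(pick("end")),
    ref = normalize_allele(pick("ref")),
    alt = normalize_allele(pick("alt")),
    gene = normalize_missing(pick("gene")),
    variant_class = normalize_variant_class(pick("variant_class")),
    depth = as_int(pick("depth")),
    exac_eas_freq = as_num(pick("exac_eas_freq")),
    vest_indel_score = as_num(pick("vest_indel_score")),
    vest_indel_p = as_num(pick("vest_indel_p")),
    aa_change = normalize_missing(pick("aa_change")),
    stringsAsFactors = FALSE
  )
  present_tools <- character(0)
  for (tool in predictor_tools()) {
    col <- unname(map[tool])
    if (!is.na(col) && col %in% names(raw)) {
      out[[tool]] <- normalize_missing(raw[[col]])
      present_tools <- c(present_tools, tool)
    } else {
      out[[tool]] <- rep(NA_character_, nrow(out))
    }
  }

  # sample suffix convention fills in what explicit columns do not provide
  parsed <- parse_sample_id(out$sample_id)
  out$tumor_group <- ifelse(is.na(out$tumor_group), parsed$tumor_group,
                            tolower(out$tumor_group))
  out$patient_id <- ifelse(is.na(out$patient_id), parsed$patient_id,
                           out$patient_id)

  bad_group <- !is.na(out$tumor_group) &
    !out$tumor_group %in% c("primary", "metastatic")
  if (any(bad_group)) {
    stop("unrecognized tumor_group value(s): ",
         paste(unique(out$tumor_group[bad_group]), collapse = ", "))
  }

  key <- paste(out$sample_id, out$chrom, out$start, out$ref, out$alt,
               sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicated (sample, chrom, start, ref, alt) row(s); ",
            "keeping first occurrence")
    out <- out[!duplicated(key), , drop = FALSE]
  }

  rownames(out) <- NULL
  attr(out, "predictor_cols") <- present_tools
  out
}

#' Write a variant table in the canonical TSV layout
#'
#' Missing values are written as "." so that a write/read round trip
#' preserves all non-missing fields exactly.
#'
#' @param variants Variant table as returned by [read_variant_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  cols <- c(variant_core_cols(), predictor_tools())
  out <- variants[, intersect(cols, names(variants)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' Expects one row per patient with columns `patient_id` (or `Sample ID`),
#' `age`, `tnm`, `er`, `pr`, `her2`, `dfs_months` (or `DFS (months)`), and
#' optionally `event` (1/TRUE when relapse was observed). "N.A." and "."
#' map to missing. When no `event` column is present every patient is
#' treated as having relapsed, the natural reading for a locoregional
#' recurrence cohort in which DFS records the time to the observed relapse.
#'
#' @param path Path to the delimited file (TSV or CSV; header required).
#' @return A `data.frame` with columns `patient_id`, `age`, `tnm`, `er`,
#'   `pr`, `her2`, `dfs_months`, `event`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  raw <- read_delim_guess(path)
  names(raw) <- tolower(names(raw))
  grab <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    rep(NA_character_, nrow(raw))
  }
  id <- normalize_missing(grab("patient_id", "sample id", "sample_id",
                               "patient"))
  if (nrow(raw) > 0 && all(is.na(id))) {
    stop("clinical table is missing a patient identifier column")
  }
  out <- data.frame(
    patient_id = id,
    age = as_num(grab("age")),
    tnm = normalize_missing(grab("tnm", "tnm of initial diagnosis")),
    er = normalize_missing(grab("er")),
    pr = normalize_missing(grab("pr")),
    her2 = normalize_missing(grab("her2")),
    dfs_months = as_num(grab("dfs_months", "dfs (months)", "dfs")),
    stringsAsFactors = FALSE
  )
  ev <- grab("event")
  out$event <- if (all(is.na(ev))) rep(TRUE, nrow(out)) else {
    tolower(normalize_missing(ev)) %in% c("1", "true", "yes")
  }
  if (any(!is.na(out$dfs_months) & out$dfs_months < 0)) {
    stop("negative dfs_months in clinical table")
  }
  if (anyDuplicated(out$patient_id[!is.na(out$patient_id)])) {
    stop("duplicated patient_id in clinical table")
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the analysis report bundle
#'
#' Emits a per-variant audit table, the gene recurrence table, per-gene
#' survival comparisons, and a machine-readable JSON summary (counts by
#' variant class and tumor group, susceptible gene lists, test statistics).
#' Output is deterministic: fixed column order, fixed gene ordering, no
#' timestamps, so identical inputs give byte-identical files.
#'
#' @param verdicts Verdict table from [classify_variants()] (may have zero
#'   rows).
#' @param recurrences Recurrence table from [call_susceptible()], or NULL.
#' @param survival_results Named list of objects from
#'   [wilcoxon_rank_sum()] (one per gene), or NULL.
#' @param dir Output directory (created if absent).
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(verdicts, recurrences = NULL,
                         survival_results = NULL, dir) {
  if (is.null(verdicts)) stop("verdicts must not be NULL")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)

  audit <- file.path(dir, "variant_audit.tsv")
  keep <- c("sample_id", "patient_id", "tumor_group", "chrom", "start",
            "end", "ref", "alt", "gene", "variant_class", "depth",
            "exac_eas_freq", "deleterious", "route", "votes_damaging",
            "reasons")
  vt <- verdicts[, intersect(keep, names(verdicts)), drop = FALSE]
  utils::write.table(vt, audit, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  files <- c(files, audit)

  if (!is.null(recurrences)) {
    rec <- file.path(dir, "gene_recurrence.tsv")
    rt <- recurrences[, c("gene", "n_primary", "n_metastatic",
                          "susceptible_primary", "susceptible_metastatic",
                          "shared"), drop = FALSE]
    utils::write.table(rt, rec, sep = "\t", quote = FALSE, na = ".",
                       row.names = FALSE)
    files <- c(files, rec)
  }

  surv_rows <- NULL
  if (!is.null(survival_results) && length(survival_results) > 0) {
    surv_rows <- do.call(rbind, lapply(names(survival_results), function(g) {
      s <- survival_results[[g]]
      data.frame(gene = g, n_mutant = s$n, n_wildtype = s$m,
                 mean_mutant = s$mean_x, mean_wildtype = s$mean_y,
                 u_statistic = s$u_statistic, p_two_tailed = s$p_two_tailed,
                 method = s$method, stringsAsFactors = FALSE)
    }))
    surv_rows <- surv_rows[order(surv_rows$gene), , drop = FALSE]
    sv <- file.path(dir, "survival_comparisons.tsv")
    utils::write.table(surv_rows, sv, sep = "\t", quote = FALSE, na = ".",
                       row.names = FALSE)
    files <- c(files, sv)
  }

  counts <- summarize_by_class(verdicts)
  summary <- list(
    n_variants = nrow(verdicts),
    n_deleterious = sum(verdicts$deleterious %||% logical(0)),
    deleterious_by_class = counts,
    susceptible_genes = if (is.null(recurrences)) character(0) else
      recurrences$gene,
    survival = surv_rows
  )
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, js)
  invisible(files)
}
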
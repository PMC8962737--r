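#' Names of the registered pathogenicity-prediction tools
#'
#' The consensus vote is taken over a fixed registry of 15 tools commonly
#' distributed with dbNSFP annotations. Predictor columns in a variant table
#' use exactly these names.
#'
#' @return Character vector of 15 tool names.
#' @export
predictor_tools <- function() {
  c("SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR", "LRT", "MutationTaster",
    "MutationAssessor", "FATHMM", "PROVEAN", "VEST3", "MetaSVM", "MetaLR",
    "M_CAP", "CADD", "FATHMM_MKL", "fitCons")
}

#' Default damaging-call rules for the 15-tool registry
#'
#' Categorical tools vote "damaging" when their call is in the tool's
#' damaging category set (dbNSFP conventions: SIFT "D"; PolyPhen-2 "D"/"P";
#' LRT "D"; MutationTaster "A"/"D"; MutationAssessor "H"/"M"; FATHMM "D";
#' PROVEAN "D"; MetaSVM/MetaLR/M-CAP/FATHMM-MKL "D"). Score-only tools vote
#' by threshold: VEST3 >= 0.5, CADD phred >= 20, fitCons >= 0.7. All rules
#' can be overridden by supplying a modified registry to
#' [count_damaging_votes()] or [classify_variants()].
#'
#' @return Named list of rules; each rule has `tool`, `mode`
#'   ("categorical" or "threshold"), and either `damaging_categories` or
#'   `threshold` + `direction` ("ge"/"le").
#' @export
default_predictor_rules <- function() {
  cat_rule <- function(tool, cats) {
    list(tool = tool, mode = "categorical", damaging_categories = cats)
  }
  thr_rule <- function(tool, threshold, direction = "ge") {
    list(tool = tool, mode = "threshold", threshold = threshold,
         direction = direction)
  }
  rules <- list(
    cat_rule("SIFT", "D"),
    cat_rule("Polyphen2_HDIV", c("D", "P")),
    cat_rule("Polyphen2_HVAR", c("D", "P")),
    cat_rule("LRT", "D"),
    cat_rule("MutationTaster", c("A", "D")),
    cat_rule("MutationAssessor", c("H", "M")),
    cat_rule("FATHMM", "D"),
    cat_rule("PROVEAN", "D"),
    thr_rule("VEST3", 0.5),
    cat_rule("MetaSVM", "D"),
    cat_rule("MetaLR", "D"),
    cat_rule("M_CAP", "D"),
    thr_rule("CADD", 20),
    cat_rule("FATHMM_MKL", "D"),
    thr_rule("fitCons", 0.7)
  )
  names(rules) <- vapply(rules, `[[`, character(1), "tool")
  stopifnot(identical(names(rules), predictor_tools()))
  rules
}

apply_predictor_rule <- function(rule, calls) {
  # calls: character vector of raw calls/scores; NA and "." are missing
  calls[calls %in% c(".", "")] <- NA_character_
  if (rule$mode == "categorical") {
    damaging <- calls %in% rule$damaging_categories
  } else {
    score <- suppressWarnings(as.numeric(calls))
    damaging <- if (identical(rule$direction, "le")) {
      !is.na(score) & score <= rule$threshold
    } else {
      !is.na(score) & score >= rule$threshold
    }
  }
  damaging & !is.na(calls)
}

#' Count damaging votes across the predictor registry
#'
#' Applies each registered rule to the matching predictor column of the
#' variant table and counts, per variant, how many tools call it damaging.
#' Missing calls (NA, ".", empty string) and absent columns contribute no
#' vote; the denominator stays at the registry size. Predictor columns in
#' the table (as recorded in its `predictor_cols` attribute) that are not in
#' the registry trigger a warning and are ignored.
#'
#' @param variants Variant table (data.frame) with predictor columns named
#'   by tool.
#' @param rules Rule registry, as from [default_predictor_rules()].
#' @return Integer vector of votes in `[0, length(rules)]`, one per row.
#' @export
count_damaging_votes <- function(variants, rules = default_predictor_rules()) {
  known <- attr(variants, "predictor_cols")
  if (!is.null(known)) {
    extra <- setdiff(known, names(rules))
    if (length(extra) > 0L) {
      warning("ignoring unregistered predictor column(s): ",
              paste(extra, collapse = ", "))
    }
  }
  votes <- integer(nrow(variants))
  for (rule in rules) {
    if (!rule$tool %in% names(variants)) next
    votes <- votes + as.integer(
      apply_predictor_rule(rule, as.character(variants[[rule$tool]]))
    )
  }
  votes
}
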
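#' Tally patients with deleterious mutations per gene and tumor group
#'
#' A patient is counted once per gene per tumor group no matter how many
#' qualifying variants they carry, matching the paired design in which each
#' patient contributes one primary and one metastatic sample. Set
#' `by = "sample"` to count distinct samples instead (for unpaired data).
#'
#' @param verdicts Verdict table from [classify_variants()]; only rows with
#'   `deleterious = TRUE` contribute.
#' @param by Count distinct "patient" ids (default) or "sample" ids.
#' @return `data.frame(gene, n_primary, n_metastatic)` with list columns
#'   `patients_primary` and `patients_metastatic` holding the sorted id
#'   sets; genes sorted alphabetically.
#' @export
tally_gene_patients <- function(verdicts, by = c("patient", "sample")) {
  by <- match.arg(by)
  idcol <- if (by == "patient") "patient_id" else "sample_id"
  empty <- data.frame(gene = character(0), n_primary = integer(0),
                      n_metastatic = integer(0), stringsAsFactors = FALSE)
  empty$patients_primary <- list()
  empty$patients_metastatic <- list()
  if (nrow(verdicts) == 0 || !any(verdicts$deleterious)) return(empty)
  del <- verdicts[verdicts$deleterious & !is.na(verdicts$gene), ,
                  drop = FALSE]
  if (nrow(del) == 0) return(empty)
  genes <- sort(unique(del$gene))
  ids_for <- function(g, grp) {
    sort(unique(del[[idcol]][del$gene == g &
                               !is.na(del$tumor_group) &
                               del$tumor_group == grp]))
  }
  pp <- lapply(genes, ids_for, grp = "primary")
  pm <- lapply(genes, ids_for, grp = "metastatic")
  out <- data.frame(gene = genes,
                    n_primary = lengths(pp),
                    n_metastatic = lengths(pm),
                    stringsAsFactors = FALSE)
  out$patients_primary <- pp
  out$patients_metastatic <- pm
  out
}

#' Call susceptible genes by recurrence
#'
#' A gene is susceptible within a tumor group when deleterious mutations
#' occur in at least `min_patients` patients of that group. Mode "shared"
#' keeps genes susceptible in both groups; mode "either" keeps genes
#' susceptible in at least one.
#'
#' @param tallies Output of [tally_gene_patients()].
#' @param min_patients Recurrence threshold (default 2).
#' @param mode "shared" (default) or "either".
#' @return The tally table restricted to the called genes, with logical
#'   columns `susceptible_primary`, `susceptible_metastatic`, `shared`,
#'   sorted by decreasing total patient count then gene symbol.
#' @export
call_susceptible <- function(tallies, min_patients = 2L,
                             mode = c("shared", "either")) {
  mode <- match.arg(mode)
  stopifnot(min_patients >= 1)
  out <- tallies
  out$susceptible_primary <- out$n_primary >= min_patients
  out$susceptible_metastatic <- out$n_metastatic >= min_patients
  out$shared <- out$susceptible_primary & out$susceptible_metastatic
  keep <- if (mode == "shared") out$shared else
    out$susceptible_primary | out$susceptible_metastatic
  out <- out[keep, , drop = FALSE]
  ord <- order(-(out$n_primary + out$n_metastatic), out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
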
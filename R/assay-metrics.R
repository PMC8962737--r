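#' Xenograft tumor volume
#'
#' `V = 0.5 * L * W^2` in mm^3, with W the smaller caliper diameter. If the
#' arguments arrive reversed they are swapped with a warning.
#'
#' @param length_mm,width_mm Caliper diameters in mm.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0)) {
    stop("tumor dimensions must be non-negative")
  }
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length; swapping to keep W the smaller diameter")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  0.5 * length_mm * width_mm^2
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target transcript (normalized to a reference gene) in
#' condition A relative to condition B:
#' `2^-((Ct_target_A - Ct_ref_A) - (Ct_target_B - Ct_ref_B))`.
#'
#' @param ct_target_a,ct_ref_a Cycle thresholds in condition A.
#' @param ct_target_b,ct_ref_b Cycle thresholds in condition B.
#' @return Fold change (1 = no change).
#' @export
fold_change_ddct <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) {
  stopifnot(is.finite(ct_target_a), is.finite(ct_ref_a),
            is.finite(ct_target_b), is.finite(ct_ref_b))
  2^-((ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b))
}

#' Wound-healing percentage
#'
#' `(initial area - area at time t) / initial area * 100`.
#'
#' @param area_initial Scratch area at time 0 (must be positive).
#' @param area_t Scratch area at the later time point.
#' @return Percent closure (100 = fully closed).
#' @export
wound_healing_pct <- function(area_initial, area_t) {
  if (any(area_initial <= 0)) stop("area_initial must be positive")
  (area_initial - area_t) / area_initial * 100
}

#' Cell growth inhibition rate from CCK-8 optical densities
#'
#' `(OD_control - OD_experimental) / OD_control * 100`.
#'
#' @param od_control Control-group optical density (must be positive).
#' @param od_experimental Experimental-group optical density.
#' @return Percent reduction relative to control.
#' @export
growth_rate_pct <- function(od_control, od_experimental) {
  if (any(od_control <= 0)) stop("od_control must be positive")
  (od_control - od_experimental) / od_control * 100
}

#' Average optical density of an immunohistochemistry region
#'
#' `AOD = IOD / Area`, the integrated optical density per unit area.
#'
#' @param iod Integrated optical density.
#' @param area Region area (must be positive).
#' @return AOD.
#' @export
average_optical_density <- function(iod, area) {
  if (any(area <= 0)) stop("area must be positive")
  iod / area
}
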
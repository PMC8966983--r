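#' Classify cohort cell lines as drug-sensitive or resistant
#'
#' A line is sensitive when its IC50 is below 20% of the cohort median IC50;
#' the median is taken over uncensored IC50s only, since censored bounds
#' would bias it upward. Lines with a censored IC50 (bound at the maximum
#' tested dose) are labelled resistant: their bound exceeds any threshold
#' below the top dose.
#'
#' @param records data.frame with columns `cell_line`, `ic50` (uM) and
#'   `censored` (logical); typically also `auc` and `tissue_class`.
#' @param fraction Sensitivity threshold as a fraction of the median IC50
#'   (default 0.2).
#' @return The records with a `sensitivity` column
#'   (`"sensitive"`/`"resistant"`) appended.
#' @export
classify_sensitivity <- function(records, fraction = 0.2) {
  if (!all(c("cell_line", "ic50", "censored") %in% names(records))) {
    stop("records need columns cell_line, ic50, censored")
  }
  unc <- records$ic50[!records$censored]
  if (length(unc) < 3) {
    stop("need >= 3 uncensored IC50s to classify sensitivity (have ",
         length(unc), ")")
  }
  threshold <- fraction * stats::median(unc)
  records$sensitivity <- ifelse(
    !records$censored & records$ic50 < threshold, "sensitive", "resistant"
  )
  attr(records, "ic50_threshold") <- threshold
  records
}

#' Cohort differential-AUC table
#'
#' Orders cohort records by normalized AUC (most sensitive first) and marks
#' the no-effect reference: an AUC of 1 corresponds to a flat, drug-free
#' response, so lines at or above it show no net drug effect.
#'
#' @param records data.frame with at least `cell_line` and `auc`; a
#'   `tissue_class` column (`"tumor"`/`"matched_normal"`) is carried
#'   through when present.
#' @return The records sorted by ascending AUC with a logical
#'   `no_drug_effect` column (`auc >= 1`).
#' @export
cohort_auc_table <- function(records) {
  if (nrow(records) == 0) {
    records$no_drug_effect <- logical(0)
    return(records)
  }
  if (!"auc" %in% names(records)) stop("records need an auc column")
  records <- records[order(records$auc), , drop = FALSE]
  records$no_drug_effect <- records$auc >= 1
  rownames(records) <- NULL
  records
}
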
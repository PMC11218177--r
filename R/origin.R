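# Multicentric (MC) vs metastatic (ME) origin calling and group comparison.
# The two origin models occupy widely separated shared-fraction bands in
# paired-foci cohorts (near zero for independent clones, a large trunk for
# metastatic spread), so a single threshold inside the gap classifies them.

#' Call the clonal origin model of one patient
#'
#' Labels a patient multicentric (MC) when the shared somatic SNV/indel
#' fraction is strictly below `threshold`, metastatic (ME) otherwise.
#' A fraction exactly at the threshold is called ME: declaring a pair of
#' foci independent tumors is the stronger claim, so ties go the other way.
#'
#' @param summary a [sharing_summary()] result (or any list with
#'   `patient_id` and `shared_fraction_snv`).
#' @param threshold MC/ME decision threshold in (0, 1); default 0.10, which
#'   sits inside the empirical gap between the two origin bands.
#' @return one-row data.frame: `patient_id`, `label`,
#'   `shared_fraction_snv`, `threshold_used`, `note`.
#' @export
classify_origin <- function(summary, threshold = 0.10) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop_input("classify_origin: threshold must be in (0, 1)")
  }
  f <- summary$shared_fraction_snv
  data.frame(
    patient_id = summary$patient_id,
    label = if (f < threshold) "MC" else "ME",
    shared_fraction_snv = f,
    threshold_used = threshold,
    note = if (isTRUE(summary$empty_denominator))
      "empty denominator; fraction reported as 0" else "",
    stringsAsFactors = FALSE
  )
}

#' Cohort origin report with group comparisons
#'
#' Assembles the per-patient shared fractions (SNV, CNV-gene and SV
#' channels) with their origin labels and compares the MC and ME groups on
#' each channel with the exact rank-sum test. A channel's p-value is `NA`
#' (with a warning) when either group is empty.
#'
#' @param calls data.frame of per-patient origin calls
#'   (rows from [classify_origin()]).
#' @param fractions data.frame with `patient_id`,
#'   `shared_fraction_snv`, `shared_fraction_cnv_genes`,
#'   `shared_fraction_sv`.
#' @return list with `table` (per-patient fractions + labels, ordered by
#'   patient id) and `p_values` (named: snv, cnv_genes, sv).
#' @export
cohort_report <- function(calls, fractions) {
  if (nrow(calls) < 2) stop_input("cohort_report: need >= 2 patients")
  tab <- merge(fractions, calls[, c("patient_id", "label")],
               by = "patient_id")
  tab <- tab[order(tab$patient_id), , drop = FALSE]
  rownames(tab) <- NULL
  channel_p <- function(col) {
    x <- tab[[col]][tab$label == "MC"]
    y <- tab[[col]][tab$label == "ME"]
    if (length(x) == 0 || length(y) == 0) {
      warning("cohort_report: a group has zero members; p-value for ",
              col, " reported as NA", call. = FALSE)
      return(NA_real_)
    }
    exact_rank_sum(x, y)$p_value
  }
  p <- c(snv = channel_p("shared_fraction_snv"),
         cnv_genes = channel_p("shared_fraction_cnv_genes"),
         sv = channel_p("shared_fraction_sv"))
  list(table = tab, p_values = p)
}
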
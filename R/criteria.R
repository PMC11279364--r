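# Rule-based metabolic-syndrome diagnosis: ATP III and IDF.
#
# Component thresholds exactly as printed in the source definitions:
#  - ATP III: WC >= 102/88 cm (M/F); Glu >= 110 mg/dL or diabetes dx;
#    TG >= 150 mg/dL (no treatment clause); BP >= 130/85 or hypertension dx;
#    HDL < 40/50 mg/dL (M/F).  Positive iff >= 3 of 5.
#  - IDF: central obesity WC >= 90/80 cm (M/F) is the mandatory gate, plus
#    >= 2 of: TG >= 150 or TG-lowering medication; HDL < 40/50 (no treatment
#    clause); BP >= 130/85 or hypertension dx; Glu >= 100 or diabetes dx.
# "BP >= 130/85" is read as SBP >= 130 OR DBP >= 85.  HDL thresholds are
# strict ('<'); all others inclusive ('>=').

.check_criteria_fields <- function(cohort) {
  need <- c("sex", "wc_cm", "sbp", "dbp", "hdl_mgdl", "tg_mgdl", "glu_mgdl",
            "dx_diabetes", "dx_hypertension", "tx_tg")
  for (f in need) {
    if (is.null(cohort[[f]])) stop("missing required field: '", f, "'")
    if (any(is.na(cohort[[f]]))) stop("missing values in required field: '", f, "'")
  }
  invisible(cohort)
}

.bp_component <- function(cohort) {
  cohort$sbp >= 130 | cohort$dbp >= 85 | cohort$dx_hypertension
}

.hdl_component <- function(cohort) {
  thr <- ifelse(cohort$sex == "male", 40, 50)
  cohort$hdl_mgdl < thr
}

#' ATP III metabolic-syndrome diagnosis
#'
#' @param cohort Cohort data.frame that passed eligibility (no missing
#'   required fields).
#' @return A data.frame with the five component logicals
#'   (`central_obesity`, `high_tg`, `low_hdl`, `high_bp`, `high_glu`),
#'   `n_components` (0-5) and `positive` (TRUE iff >= 3 components).
#' @export
atp_iii <- function(cohort) {
  .check_criteria_fields(cohort)
  comp <- data.frame(
    central_obesity = cohort$wc_cm >= ifelse(cohort$sex == "male", 102, 88),
    high_tg = cohort$tg_mgdl >= 150,
    low_hdl = .hdl_component(cohort),
    high_bp = .bp_component(cohort),
    high_glu = cohort$glu_mgdl >= 110 | cohort$dx_diabetes
  )
  comp$n_components <- rowSums(comp)
  comp$positive <- comp$n_components >= 3
  comp
}

#' IDF metabolic-syndrome diagnosis
#'
#' Central obesity is mandatory; a participant below the waist threshold is
#' negative regardless of the other components.
#'
#' @inheritParams atp_iii
#' @return As [atp_iii()]; `positive` is TRUE iff `central_obesity` and at
#'   least 2 of the remaining four components.  `n_components` counts all
#'   five true components.
#' @export
idf <- function(cohort) {
  .check_criteria_fields(cohort)
  comp <- data.frame(
    central_obesity = cohort$wc_cm >= ifelse(cohort$sex == "male", 90, 80),
    high_tg = cohort$tg_mgdl >= 150 | cohort$tx_tg,
    low_hdl = .hdl_component(cohort),
    high_bp = .bp_component(cohort),
    high_glu = cohort$glu_mgdl >= 100 | cohort$dx_diabetes
  )
  comp$n_components <- rowSums(comp)
  others <- comp$high_tg + comp$low_hdl + comp$high_bp + comp$high_glu
  comp$positive <- comp$central_obesity & others >= 2
  comp
}

#' Per-participant labels under both criteria
#'
#' @inheritParams atp_iii
#' @return A data.frame with `id`, `atp3_positive`, `idf_positive` and the
#'   ten component columns prefixed `atp3_` / `idf_`.
#' @export
mets_labels <- function(cohort) {
  a <- atp_iii(cohort)
  i <- idf(cohort)
  comp_cols <- c("central_obesity", "high_tg", "low_hdl", "high_bp", "high_glu")
  out <- data.frame(id = cohort$id,
                    atp3_positive = a$positive,
                    idf_positive = i$positive,
                    stringsAsFactors = FALSE)
  for (cc in comp_cols) out[[paste0("atp3_", cc)]] <- a[[cc]]
  for (cc in comp_cols) out[[paste0("idf_", cc)]] <- i[[cc]]
  out
}

#' Diagnose under a named criterion
#'
#' @inheritParams atp_iii
#' @param criterion `"ATP_III"` or `"IDF"`.
#' @return Logical vector of positives.
#' @export
diagnose <- function(cohort, criterion = c("ATP_III", "IDF")) {
  criterion <- match.arg(criterion)
  switch(criterion, ATP_III = atp_iii(cohort)$positive,
         IDF = idf(cohort)$positive)
}
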
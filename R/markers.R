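# The ten surrogate insulin-resistance / obesity indices.
#
# All inputs are mg/dL for biochemistry, cm for waist, m for height,
# kg/m^2 for BMI.  LAP and VAI need triglycerides and HDL in mmol/L; the
# conversion happens internally with the standard molar factors.  All
# logarithms are natural and no rounding happens inside formulas.

#' Marker identifiers and orientations
#'
#' SPISE measures insulin *sensitivity*, so lower values indicate disease;
#' every other index is higher-is-worse.
#'
#' @return Named character vector mapping marker id to
#'   `"higher_is_positive"` or `"lower_is_positive"`.
#' @export
marker_orientations <- function() {
  c(SPISE = "lower_is_positive",
    METS_IR = "higher_is_positive",
    TG_HDL = "higher_is_positive",
    TYG = "higher_is_positive",
    LAP = "higher_is_positive",
    VAI = "higher_is_positive",
    METS_VF = "higher_is_positive",
    VAT = "higher_is_positive",
    ABSI = "higher_is_positive",
    BRI = "higher_is_positive")
}

#' All marker identifiers
#' @return Character vector of the ten marker ids.
#' @export
marker_ids <- function() names(marker_orientations())

# Standard molar conversion factors (mg/dL -> mmol/L).
.TG_MGDL_PER_MMOL <- 88.57
.CHOL_MGDL_PER_MMOL <- 38.67

#' Convert mg/dL to mmol/L
#'
#' @param value Positive numeric vector in mg/dL.
#' @param analyte `"triglycerides"` (divisor 88.57) or `"cholesterol"`
#'   (divisor 38.67; used for HDL).
#' @return Value in mmol/L.
#' @export
mgdl_to_mmol <- function(value, analyte = c("triglycerides", "cholesterol")) {
  analyte <- match.arg(analyte)
  .check_pos(value, "value")
  value / switch(analyte,
                 triglycerides = .TG_MGDL_PER_MMOL,
                 cholesterol = .CHOL_MGDL_PER_MMOL)
}

.check_pos <- function(x, what) {
  if (any(is.na(x)) || any(x <= 0)) stop(what, " must be strictly positive")
  invisible(x)
}

#' Single-point insulin sensitivity estimator (SPISE)
#'
#' `600 * HDL^0.185 / (TG^0.2 * BMI^1.338)`; the whole power product is the
#' denominator.  Lower values indicate metabolic syndrome.
#'
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg Triglycerides, mg/dL.
#' @param bmi Body mass index, kg/m^2.
#' @return SPISE values.
#' @export
spise <- function(hdl, tg, bmi) {
  .check_pos(hdl, "hdl"); .check_pos(tg, "tg"); .check_pos(bmi, "bmi")
  600 * hdl^0.185 / (tg^0.2 * bmi^1.338)
}

#' Metabolic score for insulin resistance (METS-IR)
#'
#' `ln(2*Glu + TG) * BMI / ln(HDL)`, natural logs, everything mg/dL.
#' HDL must exceed 1 mg/dL so the log denominator is positive.
#'
#' @param glu Fasting glucose, mg/dL.
#' @param tg Triglycerides, mg/dL.
#' @param bmi Body mass index, kg/m^2.
#' @param hdl HDL cholesterol, mg/dL (> 1).
#' @return METS-IR values.
#' @export
mets_ir <- function(glu, tg, bmi, hdl) {
  .check_pos(glu, "glu"); .check_pos(tg, "tg"); .check_pos(bmi, "bmi")
  if (any(is.na(hdl)) || any(hdl <= 1)) stop("hdl must exceed 1 mg/dL")
  log(2 * glu + tg) * bmi / log(hdl)
}

#' Triglyceride/HDL ratio
#' @param tg Triglycerides, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @return TG/HDL ratio (dimensionless).
#' @export
tg_hdl <- function(tg, hdl) {
  .check_pos(tg, "tg"); .check_pos(hdl, "hdl")
  tg / hdl
}

#' Triglyceride-glucose index (TyG)
#'
#' Implemented exactly as the evaluated form `ln(TG * Glu) / 2` (values
#' around 4.6-4.9 on mg/dL inputs), not the common `ln(TG * Glu / 2)`.
#'
#' @param tg Triglycerides, mg/dL.
#' @param glu Fasting glucose, mg/dL.
#' @return TyG values.
#' @export
tyg <- function(tg, glu) {
  .check_pos(tg, "tg"); .check_pos(glu, "glu")
  log(tg * glu) / 2
}

#' Lipid accumulation product (LAP)
#'
#' `(WC - 65) * TG_mmol` for men, `(WC - 58) * TG_mmol` for women.
#' Triglycerides are converted from mg/dL internally.  Negative values are
#' allowed when WC is below the sex offset.
#'
#' @param sex `"male"`/`"female"` vector.
#' @param wc Waist circumference, cm.
#' @param tg Triglycerides, mg/dL.
#' @return LAP values.
#' @export
lap <- function(sex, wc, tg) {
  .check_pos(wc, "wc"); .check_pos(tg, "tg")
  offset <- ifelse(sex == "male", 65, 58)
  (wc - offset) * mgdl_to_mmol(tg, "triglycerides")
}

#' Visceral adiposity index (VAI)
#'
#' Product of a WC/BMI factor, a triglyceride factor and an HDL factor with
#' sex-specific constants: men `WC/(1.88*BMI + 39.68) * (TG/1.03) *
#' (1.31/HDL)`, women `WC/(1.89*BMI + 36.58) * (TG/0.81) * (1.52/HDL)`,
#' with TG and HDL in mmol/L (converted internally from mg/dL).  The
#' women's form is multiplicative by default; `women_as_printed = TRUE`
#' instead *sums* the three factors, reproducing a typographical variant of
#' the formula as typeset in some sources.
#'
#' @param sex `"male"`/`"female"` vector.
#' @param wc Waist circumference, cm.
#' @param bmi Body mass index, kg/m^2.
#' @param tg Triglycerides, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param women_as_printed Logical; see Details.  Default `FALSE`.
#' @return VAI values.
#' @export
vai <- function(sex, wc, bmi, tg, hdl, women_as_printed = FALSE) {
  .check_pos(wc, "wc"); .check_pos(bmi, "bmi")
  tgm <- mgdl_to_mmol(tg, "triglycerides")
  hdlm <- mgdl_to_mmol(hdl, "cholesterol")
  male <- sex == "male"
  f1 <- ifelse(male, wc / (1.88 * bmi + 39.68), wc / (1.89 * bmi + 36.58))
  f2 <- ifelse(male, tgm / 1.03, tgm / 0.81)
  f3 <- ifelse(male, 1.31 / hdlm, 1.52 / hdlm)
  out <- f1 * f2 * f3
  if (women_as_printed) out[!male] <- (f1 + f2 + f3)[!male]
  out
}

#' Metabolic score for visceral fat (METS-VF)
#'
#' `4.466 + 0.011*ln(METS-IR)^3 + 3.239*ln(WHtR)^3 + 0.319*Sex +
#' 0.594*ln(Age)` with Sex = 1 for men, 0 for women; cubes apply to the
#' logs.
#'
#' @param mets_ir_value METS-IR values (> 0), see [mets_ir()].
#' @param whtr Waist-to-height ratio (same units top and bottom).
#' @param sex `"male"`/`"female"` vector.
#' @param age Age in years, >= 20.
#' @return METS-VF values.
#' @export
mets_vf <- function(mets_ir_value, whtr, sex, age) {
  .check_pos(mets_ir_value, "mets_ir_value"); .check_pos(whtr, "whtr")
  if (any(is.na(age)) || any(age < 20)) stop("age must be >= 20")
  4.466 + 0.011 * log(mets_ir_value)^3 + 3.239 * log(whtr)^3 +
    0.319 * (sex == "male") + 0.594 * log(age)
}

#' Visceral adipose tissue estimate (VAT)
#'
#' `exp(METS-VF)`: the exponent is the full METS-VF expression, making VAT
#' a strictly monotone transform of METS-VF (their ROC curves coincide).
#'
#' @param mets_vf_value METS-VF values, see [mets_vf()].
#' @return VAT values.
#' @export
vat <- function(mets_vf_value) {
  if (any(!is.finite(mets_vf_value))) stop("mets_vf_value must be finite")
  exp(mets_vf_value)
}

#' A body shape index (ABSI)
#'
#' `WC_m / (BMI^(2/3) * height_m^(1/2))` with waist and height in meters
#' (waist is supplied in cm and converted).  Typical adult values are
#' around 0.07-0.08.
#'
#' @param wc Waist circumference, cm.
#' @param bmi Body mass index, kg/m^2.
#' @param height Height, m.
#' @return ABSI values.
#' @export
absi <- function(wc, bmi, height) {
  .check_pos(wc, "wc"); .check_pos(bmi, "bmi"); .check_pos(height, "height")
  (wc / 100) / (bmi^(2 / 3) * height^(1 / 2))
}

#' Body roundness index (BRI)
#'
#' `364.2 - 365.5 * sqrt(1 - (WC_m/(2*pi))^2 / (0.5*height)^2)`, the
#' eccentricity of the body ellipse.  Requires `WC_m < pi * height`.
#'
#' @param wc Waist circumference, cm.
#' @param height Height, m.
#' @return BRI values.
#' @export
bri <- function(wc, height) {
  .check_pos(wc, "wc"); .check_pos(height, "height")
  wcm <- wc / 100
  if (any(wcm / (pi * height) >= 1))
    stop("degenerate body ellipse: wc/(pi*height) >= 1")
  364.2 - 365.5 * sqrt(1 - (wcm / (2 * pi))^2 / (0.5 * height)^2)
}

#' Compute the full ten-marker panel for a cohort
#'
#' @param cohort Cohort data.frame that passed [apply_eligibility()]
#'   (so `bmi` and `whtr` are present and all inputs non-missing).
#' @param vai_women_as_printed Passed to [vai()].
#' @return A data.frame with `id` plus one column per marker id in
#'   [marker_ids()] order.
#' @export
compute_panel <- function(cohort, vai_women_as_printed = FALSE) {
  if (is.null(cohort$whtr)) cohort <- derive_anthropometrics(cohort)
  mir <- mets_ir(cohort$glu_mgdl, cohort$tg_mgdl, cohort$bmi, cohort$hdl_mgdl)
  mvf <- mets_vf(mir, cohort$whtr, cohort$sex, cohort$age)
  data.frame(
    id = cohort$id,
    SPISE = spise(cohort$hdl_mgdl, cohort$tg_mgdl, cohort$bmi),
    METS_IR = mir,
    TG_HDL = tg_hdl(cohort$tg_mgdl, cohort$hdl_mgdl),
    TYG = tyg(cohort$tg_mgdl, cohort$glu_mgdl),
    LAP = lap(cohort$sex, cohort$wc_cm, cohort$tg_mgdl),
    VAI = vai(cohort$sex, cohort$wc_cm, cohort$bmi, cohort$tg_mgdl,
              cohort$hdl_mgdl, women_as_printed = vai_women_as_printed),
    METS_VF = mvf,
    VAT = vat(mvf),
    ABSI = absi(cohort$wc_cm, cohort$bmi, cohort$height_m),
    BRI = bri(cohort$wc_cm, cohort$height_m),
    stringsAsFactors = FALSE
  )
}
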
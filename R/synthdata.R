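# Synthetic survey-like cohorts and idealized binormal score sets.
#
# The generator emulates the marginal structure of a large Mexican adult
# nutrition survey: sex-specific location/scale for anthropometrics and
# biochemistry (triglycerides and glucose log-normal, the rest truncated
# normal), a Gaussian copula for residual correlation, and a single latent
# "metabolic risk" factor whose loadings shift waist, BMI, lipids, glucose
# and blood pressure together — the simplest mechanism that makes surrogate
# markers informative about rule-based metabolic syndrome.
#
# All randomness flows from one seed through per-variable streams (the
# stream label is the variable name), and the copula mixing matrix is upper
# triangular in a fixed variable order, so appending a new variable never
# perturbs existing draws.

# Fixed copula variable order.  Appending only.
.COPULA_VARS <- c("height", "bmi", "wc", "hdl", "tg", "glu", "sbp", "dbp", "chol")

.default_copula <- function() {
  v <- .COPULA_VARS
  R <- diag(length(v)); dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  set_r("bmi", "wc", 0.60)    # residual adiposity correlation
  set_r("bmi", "sbp", 0.15)
  set_r("wc", "sbp", 0.15)
  set_r("sbp", "dbp", 0.65)
  set_r("tg", "glu", 0.20)
  set_r("tg", "hdl", -0.35)
  set_r("chol", "tg", 0.30)
  set_r("chol", "hdl", 0.15)
  R
}

#' Specification for a synthetic cohort
#'
#' Defaults are calibrated so that a large default cohort reproduces the
#' survey's marginal medians (BMI 28.4 kg/m^2, WC 95.8 cm, TG 168 mg/dL,
#' glucose 92 mg/dL, HDL 43 mg/dL) to within a few percent, with
#' metabolic-syndrome prevalence in the 40-60% band.  Because the latent
#' risk factor has median zero and enters additively (or multiplicatively
#' on the log scale for TG/glucose), medians are set directly by the
#' per-sex location parameters.
#'
#' @param n Number of participants.
#' @param seed Integer master seed.
#' @param sex_ratio Proportion female, default 0.57.
#' @param age_weights Mixture weights of the 20-39 / 40-59 / 60+ groups.
#' @param latent_risk_sd Dispersion of the latent metabolic-risk burden, a
#'   half-normal score `latent_risk_sd * |N(0,1)|` centered on the unit
#'   half-normal median (so the default 1 leaves the marginal medians at
#'   their calibrated locations).  The burden is stochastically increasing
#'   in this knob and every loading points toward disease, so syndrome
#'   prevalence is non-decreasing in it under either criterion.
#' @param risk_loadings Named numeric vector of per-variable loadings on
#'   the risk burden (`wc`, `bmi`, `sbp`, `dbp`, `hdl` additive;
#'   `log_tg`, `log_glu` on the log scale).  A negative loading (HDL)
#'   moves the variable down with rising risk.
#' @param marginals Named list of per-sex location/residual-scale
#'   parameters; see the default for the structure.
#' @param copula Correlation matrix for the Gaussian copula over
#'   `height, bmi, wc, hdl, tg, glu, sbp, dbp, chol` (must be symmetric
#'   positive-definite).
#' @param flag_p_true,flag_p_false P(diagnosis/treatment flag | component
#'   exceeded) and P(flag | not exceeded).
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 10000, seed = 20180101,
                        sex_ratio = 0.57,
                        age_weights = c(0.379, 0.387, 0.234),
                        latent_risk_sd = 1,
                        risk_loadings = c(wc = 6, bmi = 2.5, sbp = 8, dbp = 4.5,
                                          hdl = -4, log_tg = 0.35, log_glu = 0.09),
                        marginals = NULL,
                        copula = .default_copula(),
                        flag_p_true = 0.3, flag_p_false = 0.02) {
  if (is.null(marginals)) {
    # scale is the residual (copula) dispersion; the latent risk burden
    # adds on top of it through the loadings
    marginals <- list(
      male = list(height = c(1.68, 0.07), bmi = c(27.6, 4.6), wc = c(97, 9),
                  hdl = c(40.5, 8.7), tg = c(log(175), 0.41), glu = c(log(92), 0.12),
                  sbp = c(123, 15), dbp = c(76, 9), chol = c(184, 37)),
      female = list(height = c(1.56, 0.065), bmi = c(28.9, 4.9), wc = c(95, 9),
                    hdl = c(45, 8.7), tg = c(log(162), 0.41), glu = c(log(92), 0.12),
                    sbp = c(121, 15), dbp = c(74, 9), chol = c(182, 37))
    )
  }
  if (!isTRUE(all.equal(copula, t(copula))) ||
      inherits(try(chol(copula), silent = TRUE), "try-error"))
    stop("copula matrix must be symmetric positive-definite")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  if (flag_p_true < 0 || flag_p_true > 1 || flag_p_false < 0 || flag_p_false > 1)
    stop("flag probabilities must be in [0, 1]")
  structure(list(n = n, seed = seed, sex_ratio = sex_ratio,
                 age_weights = age_weights / sum(age_weights),
                 latent_risk_sd = latent_risk_sd, risk_loadings = risk_loadings,
                 marginals = marginals, copula = copula,
                 flag_p_true = flag_p_true, flag_p_false = flag_p_false),
            class = "cohort_spec")
}

# One N(0,1) draw-vector from the stream named `label`.
.stream_norm <- function(seed, label, n) {
  .with_seed(derive_seed(seed, label), stats::rnorm(n))
}

.stream_unif <- function(seed, label, n) {
  .with_seed(derive_seed(seed, label), stats::runif(n))
}

#' Generate a synthetic cohort
#'
#' Each subject draws a latent metabolic-risk score that shifts waist, BMI,
#' triglycerides, glucose and blood pressure upward and HDL downward via
#' the spec's loadings, inducing realistic co-occurrence of the syndrome
#' components; diagnosis/treatment flags are sampled conditional on the
#' corresponding component being exceeded.  Values are clamped inside the
#' eligibility window (glucose 70-500 mg/dL, TG <= 1200 mg/dL, height
#' >= 1.30 m) so downstream filter tests control exclusions explicitly.
#' Byte-identical given the same spec (including seed).
#'
#' @param spec A [cohort_spec()].
#' @return Cohort data.frame in the canonical schema (see
#'   [cohort_columns()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n; seed <- spec$seed

  sex <- ifelse(.stream_unif(seed, "sex", n) < spec$sex_ratio, "female", "male")
  grp <- findInterval(.stream_unif(seed, "age_group", n),
                      cumsum(spec$age_weights)[1:2]) + 1L
  u_age <- .stream_unif(seed, "age", n)
  lo <- c(20, 40, 60)[grp]; hi <- c(39, 59, 84)[grp]
  age <- floor(lo + u_age * (hi - lo + 1))

  # correlated standard normals: upper-triangular mixing keeps early
  # variables unchanged when new ones are appended
  U <- chol(spec$copula[.COPULA_VARS, .COPULA_VARS])
  Zraw <- vapply(.COPULA_VARS, function(v) .stream_norm(seed, v, n),
                 numeric(n))
  Z <- Zraw %*% U
  colnames(Z) <- .COPULA_VARS

  # One-sided latent risk burden: a half-normal score, centered on the
  # unit half-normal median so the default latent_risk_sd = 1 leaves the
  # marginal medians at their calibrated locations.  Because the burden is
  # stochastically increasing in latent_risk_sd and every loading points
  # toward disease (HDL negative), each component-exceedance probability —
  # and hence syndrome prevalence under any counting rule — is
  # non-decreasing in latent_risk_sd.
  z_risk <- spec$latent_risk_sd * abs(.stream_norm(seed, "latent_risk", n)) -
    stats::qnorm(0.75)

  ld <- function(nm) if (nm %in% names(spec$risk_loadings)) spec$risk_loadings[[nm]] else 0
  draw <- function(v, loading_name = v) {
    loc <- vapply(spec$marginals[sex], function(mm) mm[[v]][1], numeric(1))
    s <- vapply(spec$marginals[sex], function(mm) mm[[v]][2], numeric(1))
    loc + ld(loading_name) * z_risk + s * Z[, v]
  }

  height <- pmin(pmax(draw("height"), 1.32), 2.05)
  bmi <- pmax(draw("bmi"), 14)
  wc <- pmax(draw("wc"), 50)
  hdl <- pmax(draw("hdl"), 15)
  sbp <- pmax(draw("sbp"), 80)
  dbp <- pmax(draw("dbp"), 40)
  chol <- pmax(draw("chol"), 80)
  tg <- pmin(pmax(exp(draw("tg", "log_tg")), 30), 1200)
  glu <- pmin(pmax(exp(draw("glu", "log_glu")), 70), 500)

  flag <- function(label, component) {
    p <- ifelse(component, spec$flag_p_true, spec$flag_p_false)
    .stream_unif(seed, label, n) < p
  }

  data.frame(
    id = sprintf("S%06d", seq_len(n)),
    sex = sex, age = age,
    weight_kg = bmi * height^2, height_m = height, bmi = bmi, wc_cm = wc,
    sbp = sbp, dbp = dbp, chol_mgdl = chol, hdl_mgdl = hdl,
    tg_mgdl = tg, glu_mgdl = glu,
    dx_diabetes = flag("dx_diabetes", glu >= 110),
    dx_hypertension = flag("dx_hypertension", sbp >= 130 | dbp >= 85),
    tx_tg = flag("tx_tg", tg >= 150),
    dx_chol = flag("dx_chol", chol >= 200),
    stringsAsFactors = FALSE
  )
}

#' Generate binormal diagnostic scores with known ROC properties
#'
#' Negatives are N(0, 1) and positives N(d, 1), so the true AUC is
#' `pnorm(d / sqrt(2))` and the maximal Youden index (attained at d/2) is
#' `2 * pnorm(d / 2) - 1`.
#'
#' @param n_pos,n_neg Class sizes, >= 1.
#' @param d Mean separation in SD units, >= 0.
#' @param seed Integer seed.
#' @return List with `scores` and logical `labels`.
#' @export
generate_binormal_scores <- function(n_pos, n_neg, d, seed = NULL) {
  stopifnot(n_pos >= 1, n_neg >= 1, d >= 0)
  .with_seed(seed, {
    list(scores = c(stats::rnorm(n_pos, mean = d), stats::rnorm(n_neg)),
         labels = c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
  })
}

#' Blank fields at random to exercise the elimination path
#'
#' Each eligible field of each record is independently set to `NA` with
#' probability `rate`.
#'
#' @param cohort Cohort data.frame.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param fields Columns eligible for blanking; defaults to the continuous
#'   measurement columns.
#' @return The cohort with injected missingness.
#' @export
inject_missingness <- function(cohort, rate, seed = NULL,
                               fields = .numeric_columns()) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(cohort)
  .with_seed(seed, {
    for (f in fields) {
      hit <- stats::runif(nrow(cohort)) < rate
      cohort[[f]][hit] <- NA
    }
  })
  cohort
}

#' Serialize / read a cohort spec as JSON
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `path` invisibly (write) or a `cohort_spec` (read).
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  x$risk_loadings <- as.list(x$risk_loadings)   # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cop <- as.matrix(x$copula)
  dimnames(cop) <- list(.COPULA_VARS, .COPULA_VARS)
  marg <- lapply(x$marginals, function(m) lapply(m, as.numeric))
  cohort_spec(n = x$n, seed = x$seed, sex_ratio = x$sex_ratio,
              age_weights = as.numeric(x$age_weights),
              latent_risk_sd = x$latent_risk_sd,
              risk_loadings = unlist(x$risk_loadings),
              marginals = marg, copula = cop,
              flag_p_true = x$flag_p_true, flag_p_false = x$flag_p_false)
}
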
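# Independent oracles and small fixture builders.  Everything here is
# deliberately brute-force and shares no code path with the package.

# All-pairs Mann-Whitney concordance with ties counted 1/2.
oracle_auc <- function(scores, labels, orientation = "higher_is_positive") {
  if (orientation == "lower_is_positive") scores <- -scores
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Exhaustive Youden maximization over every observed threshold, with the
# package's stated tie-break re-derived by explicit enumeration.
oracle_best_cutoff <- function(scores, labels, orientation = "higher_is_positive") {
  pos <- scores[labels]; neg <- scores[!labels]
  ths <- sort(unique(scores))
  yi <- vapply(ths, function(t) {
    test_pos <- if (orientation == "higher_is_positive") scores >= t else scores <= t
    mean(test_pos[labels]) + mean(!test_pos[!labels]) - 1
  }, numeric(1))
  best <- which(abs(yi - max(yi)) < 1e-12)
  i <- if (orientation == "higher_is_positive") best[1] else best[length(best)]
  list(cutoff = ths[i], yi = yi[i])
}

# Exact Clopper-Pearson coverage for (n, p) by full binomial enumeration.
oracle_cp_coverage <- function(n, p, level = 0.95) {
  cover <- 0
  for (k in 0:n) {
    ci <- clopper_pearson(k, n, level)
    if (p >= ci[1] && p <= ci[2]) cover <- cover + stats::dbinom(k, n, p)
  }
  cover
}

# Tiny hand-built eligible cohort; every field present and in range.
make_small_cohort <- function(n = 8) {
  set.seed(99)
  data.frame(
    id = sprintf("P%02d", 1:n),
    sex = rep(c("male", "female"), length.out = n),
    age = sample(20:80, n, replace = TRUE),
    weight_kg = round(runif(n, 55, 95), 1),
    height_m = round(runif(n, 1.45, 1.85), 2),
    bmi = NA_real_,
    wc_cm = round(runif(n, 70, 115), 1),
    sbp = round(runif(n, 100, 160)),
    dbp = round(runif(n, 60, 100)),
    chol_mgdl = round(runif(n, 140, 240)),
    hdl_mgdl = round(runif(n, 30, 60)),
    tg_mgdl = round(runif(n, 80, 350)),
    glu_mgdl = round(runif(n, 75, 160)),
    dx_diabetes = FALSE, dx_hypertension = FALSE,
    tx_tg = FALSE, dx_chol = FALSE,
    stringsAsFactors = FALSE
  )
}

write_cohort_csv <- function(cohort, path = tempfile(fileext = ".csv")) {
  utils::write.csv(cohort, path, row.names = FALSE)
  path
}
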
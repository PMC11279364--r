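test_that("empirical ROC enumerates the hand-derived operating points", {
  scores <- c(3, 5, 1, 4)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- empirical_roc(scores, labels)
  # t = 3: both positives called, one of two negatives below 3
  i3 <- which(roc$thresholds == 3)
  expect_equal(c(roc$se[i3], roc$sp[i3]), c(1, 0.5))
  i5 <- which(roc$thresholds == 5)
  expect_equal(c(roc$se[i5], roc$sp[i5]), c(0.5, 1))
  # sentinels give the (1,0) and (0,1) endpoints
  expect_equal(c(roc$se[1], roc$sp[1]), c(1, 0))
  expect_equal(c(roc$se[length(roc$se)], roc$sp[length(roc$sp)]), c(0, 1))
  # monotone along the curve
  expect_true(all(diff(roc$se) <= 0))
  expect_true(all(diff(roc$sp) >= 0))
  expect_error(empirical_roc(scores, rep(TRUE, 4)), "class")
})

test_that("AUC: trapezoid equals hand counts, perfect and null cases", {
  expect_equal(roc_auc(empirical_roc(c(3, 5, 1, 4), c(T, T, F, F))), 0.75)
  expect_equal(roc_auc(empirical_roc(c(10, 9, 1, 2), c(T, T, F, F))), 1)
  expect_equal(roc_auc(empirical_roc(rep(1, 10), rep(c(T, F), 5))), 0.5)
  # perfect separation passes through the (1,1) corner
  roc <- empirical_roc(c(10, 9, 1, 2), c(T, T, F, F))
  expect_true(any(roc$se == 1 & roc$sp == 1))
})

test_that("lower_is_positive mirrors higher_is_positive on negated scores", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    sc <- round(rnorm(n), 1)            # ties likely
    lb <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(lb) || all(lb)) next
    hi <- empirical_roc(sc, lb, "higher_is_positive")
    lo <- empirical_roc(-sc, lb, "lower_is_positive")
    expect_equal(roc_auc(hi), roc_auc(lo))
    oh <- optimal_cutoff(hi); ol <- optimal_cutoff(lo)
    expect_equal(oh$yi, ol$yi)
    expect_equal(oh$cutoff, -ol$cutoff)
  }
})

test_that("AUC equals the all-pairs Mann-Whitney oracle on random instances", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    sc <- sample(round(rnorm(n), 1))    # coarse grid forces ties
    lb <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(lb) || all(lb)) next
    or <- sample(c("higher_is_positive", "lower_is_positive"), 1)
    expect_equal(roc_auc(empirical_roc(sc, lb, or)), oracle_auc(sc, lb, or),
                 tolerance = 1e-12)
  }
})

test_that("optimal_cutoff equals exhaustive search with the stated tie-break", {
  # hand instance: YI ties at t=3 and t=5 (both 0.5) -> smallest wins
  opt <- optimal_cutoff(empirical_roc(c(3, 5, 1, 4), c(T, T, F, F)))
  expect_equal(opt$cutoff, 3)
  expect_equal(opt$yi, 0.5)
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(6:50, 1)
    sc <- sample(round(runif(n, 0, 5), 0))
    lb <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(lb) || all(lb)) next
    or <- sample(c("higher_is_positive", "lower_is_positive"), 1)
    got <- optimal_cutoff(empirical_roc(sc, lb, or))
    want <- oracle_best_cutoff(sc, lb, or)
    expect_equal(got$yi, want$yi, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("confusion counts follow the orientation rule and class invariants", {
  sc <- c(3, 5, 1, 4); lb <- c(T, T, F, F)
  expect_equal(confusion_at(sc, lb, 3, "higher_is_positive"),
               list(tp = 2, fp = 1, tn = 1, fn = 0))
  expect_equal(confusion_at(sc, lb, 0, "higher_is_positive")$fp, 2)
  expect_equal(confusion_at(sc, lb, 99, "higher_is_positive"),
               list(tp = 0, fp = 0, tn = 2, fn = 2))
  cc <- confusion_at(sc, lb, 3, "lower_is_positive")
  expect_equal(cc$tp + cc$fn, 2)
  expect_equal(cc$tn + cc$fp, 2)
})

test_that("accuracy measures reproduce the published men-20-39 row and identities", {
  m <- accuracy_measures(list(tp = 448, fn = 58, tn = 867, fp = 349))
  expect_equal(round(m$se, 1), 88.5)
  expect_equal(round(m$sp, 1), 71.3)
  expect_equal(round(m$ppv, 1), 56.2)
  expect_equal(round(m$npv, 1), 93.7)
  expect_equal(round(m$lrp, 2), 3.08)
  expect_equal(round(m$lrn, 2), 0.16)
  expect_equal(round(m$yi, 1), 59.8)
  # percent-scale identities at full precision
  expect_equal(m$yi, m$se + m$sp - 100)
  expect_equal(m$lrp * (100 - m$sp), m$se)
  expect_equal(m$lrn * m$sp, 100 - m$se)

  perf <- accuracy_measures(list(tp = 10, fn = 0, tn = 20, fp = 0))
  expect_equal(c(perf$se, perf$sp, perf$ppv, perf$npv, perf$yi),
               c(100, 100, 100, 100, 100))
  expect_equal(perf$lrp, Inf)         # Sp = 1: undefined ratio, not an error
  flat <- accuracy_measures(list(tp = 25, fn = 25, tn = 25, fp = 25))
  expect_equal(c(flat$se, flat$sp, flat$lrp, flat$lrn, flat$yi),
               c(50, 50, 1, 1, 0))
})

test_that("Clopper-Pearson matches the frozen spot value and boundary conventions", {
  expect_equal(clopper_pearson(0, 10)[1], 0)
  expect_equal(clopper_pearson(10, 10)[2], 1)
  expect_equal(clopper_pearson(8, 10), c(0.4439, 0.9748), tolerance = 0.0005)
  # oracle cross-check: bounds invert the exact binomial tails
  ci <- clopper_pearson(8, 10)
  expect_equal(1 - pbinom(7, 10, ci[1]), 0.025, tolerance = 1e-9)
  expect_equal(pbinom(8, 10, ci[2]), 0.025, tolerance = 1e-9)
})

test_that("bootstrap Youden CI is deterministic, degenerate-safe", {
  bn <- generate_binormal_scores(80, 80, 1.2, seed = 5)
  ci1 <- bootstrap_youden_ci(bn$scores, bn$labels, B = 200, seed = 9)
  ci2 <- bootstrap_youden_ci(bn$scores, bn$labels, B = 200, seed = 9)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_youden_ci(bn$scores, bn$labels, B = 200, seed = 10)
  expect_false(identical(ci1, ci3))
  expect_true(ci1[1] < ci1[2])
  # constant scores: YI = 0 in every replicate
  const <- rep(2, 40)
  ci0 <- bootstrap_youden_ci(const, rep(c(TRUE, FALSE), 20), B = 100, seed = 1)
  expect_equal(ci0, c(0, 0))
  expect_error(bootstrap_youden_ci(bn$scores, bn$labels, B = 50, seed = 1), "B")
})

test_that("paired-bootstrap AUC comparison: identity, symmetry, determinism", {
  bn <- generate_binormal_scores(60, 60, 1, seed = 2)
  same <- compare_auc_paired_bootstrap(bn$scores, bn$scores, bn$labels,
                                       B = 200, seed = 4)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  other <- bn$scores + rnorm(120, sd = 1.5)
  ab <- compare_auc_paired_bootstrap(bn$scores, other, bn$labels, B = 300, seed = 4)
  ba <- compare_auc_paired_bootstrap(other, bn$scores, bn$labels, B = 300, seed = 4)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  ab2 <- compare_auc_paired_bootstrap(bn$scores, other, bn$labels, B = 300, seed = 4)
  expect_identical(ab$p_value, ab2$p_value)
})

test_that("evaluate_marker composes the stages coherently", {
  bn <- generate_binormal_scores(150, 150, 1.5, seed = 6)
  rep1 <- evaluate_marker(bn$scores, bn$labels, B = 300, seed = 13)
  expect_s3_class(rep1, "mets_accuracy")
  expect_equal(rep1$yi, rep1$se + rep1$sp - 100)
  expect_equal(rep1$auc, roc_auc(empirical_roc(bn$scores, bn$labels)))
  expect_true(rep1$auc_ci[1] <= rep1$auc && rep1$auc <= rep1$auc_ci[2])
  expect_true(rep1$yi_ci[1] <= rep1$yi + 1e-9 && rep1$yi <= rep1$yi_ci[2] + 1e-9)
  # Se CI is Clopper-Pearson with n = class sizes
  k_se <- rep1$counts$tp
  expect_equal(rep1$se_ci, 100 * clopper_pearson(k_se, rep1$n_pos))
  # perfect marker
  perf <- evaluate_marker(c(rep(1, 5), rep(0, 5)), c(rep(TRUE, 5), rep(FALSE, 5)),
                          B = 0)
  expect_equal(perf$auc, 1)
  expect_equal(perf$yi, 100)
  # lower_is_positive marker reports a <= cut-off with AUC above 0.5
  lo <- evaluate_marker(-bn$scores, bn$labels, "lower_is_positive", B = 0)
  expect_equal(lo$auc, rep1$auc)
  expect_equal(lo$cutoff, -rep1$cutoff)
})
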
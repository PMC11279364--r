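# Diagnostic-accuracy engine: empirical ROC, AUC, Youden-maximal cut-off,
# accuracy measures with exact and bootstrap confidence intervals, and a
# paired-bootstrap test for two correlated ROC curves.
#
# Conventions
#  - orientation "higher_is_positive": threshold t classifies score >= t as
#    test-positive; "lower_is_positive": score <= t.
#  - candidate thresholds are the unique observed scores plus -Inf/+Inf
#    sentinels, so every curve contains the (se, sp) endpoints (1, 0) and
#    (0, 1); the reported cut-off is always an observed value.
#  - proportions are carried at full precision; the percent scale is a
#    presentation layer.

.ORIENTATIONS <- c("higher_is_positive", "lower_is_positive")

.check_two_classes <- function(labels) {
  if (any(is.na(labels))) stop("labels must not contain NA")
  if (!any(labels) || all(labels))
    stop("both a positive and a negative class are required")
  invisible(labels)
}

#' Empirical ROC curve
#'
#' @param scores Numeric vector of finite marker values.
#' @param labels Logical vector, TRUE = diseased; both classes required.
#' @param orientation `"higher_is_positive"` (score >= t positive) or
#'   `"lower_is_positive"` (score <= t positive).
#' @return An object of class `"mets_roc"`: list with `thresholds`
#'   (ascending, with -Inf/+Inf sentinels), `se`, `sp`, `orientation`,
#'   `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels,
                          orientation = c("higher_is_positive", "lower_is_positive")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  .check_two_classes(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")

  pos <- sort(scores[labels])
  neg <- sort(scores[!labels])
  n_pos <- length(pos)
  n_neg <- length(neg)
  ths <- c(-Inf, sort(unique(scores)), Inf)

  if (orientation == "higher_is_positive") {
    # positive iff score >= t
    se <- (n_pos - findInterval(ths, pos, left.open = TRUE)) / n_pos
    sp <- findInterval(ths, neg, left.open = TRUE) / n_neg
  } else {
    # positive iff score <= t
    se <- findInterval(ths, pos) / n_pos
    sp <- (n_neg - findInterval(ths, neg)) / n_neg
  }
  structure(list(thresholds = ths, se = se, sp = sp,
                 orientation = orientation, n_pos = n_pos, n_neg = n_neg),
            class = "mets_roc")
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area over (1 - sp, se), which for the empirical curve equals
#' the Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param roc A `"mets_roc"` object from [empirical_roc()].
#' @return AUC as a proportion in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "mets_roc"))
  fpr <- 1 - roc$sp
  ord <- order(fpr, roc$se)
  x <- fpr[ord]; y <- roc$se[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Fast Mann-Whitney AUC with tie-halving via midranks; orientation-aware.
.auc_mw <- function(scores, labels, orientation = "higher_is_positive") {
  if (orientation == "lower_is_positive") scores <- -scores
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Maximal Youden index and its cut-off over the unique observed scores.
# Returns list(cutoff, se, sp, yi).  Tie-break: smallest threshold when
# higher_is_positive (maximal sensitivity among ties), largest otherwise.
.max_youden <- function(pos, neg, orientation) {
  pos <- sort(pos); neg <- sort(neg)
  n_pos <- length(pos); n_neg <- length(neg)
  ths <- sort(unique(c(pos, neg)))
  if (orientation == "higher_is_positive") {
    se <- (n_pos - findInterval(ths, pos, left.open = TRUE)) / n_pos
    sp <- findInterval(ths, neg, left.open = TRUE) / n_neg
    yi <- se + sp - 1
    i <- which.max(yi)                       # first max = smallest threshold
  } else {
    se <- findInterval(ths, pos) / n_pos
    sp <- (n_neg - findInterval(ths, neg)) / n_neg
    yi <- se + sp - 1
    m <- max(yi)
    i <- max(which(yi == m))                 # last max = largest threshold
  }
  list(cutoff = ths[i], se = se[i], sp = sp[i], yi = yi[i])
}

#' Youden-optimal cut-off
#'
#' The observed-value threshold maximizing `se + sp - 1`.  Ties are broken
#' by the smallest threshold for `higher_is_positive` markers (maximal
#' sensitivity among ties) and the largest for `lower_is_positive`.
#'
#' @param roc A `"mets_roc"` object.
#' @return List with `cutoff`, `se`, `sp`, `yi` (all proportions).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "mets_roc"))
  keep <- is.finite(roc$thresholds)
  yi <- roc$se[keep] + roc$sp[keep] - 1
  ths <- roc$thresholds[keep]
  i <- if (roc$orientation == "higher_is_positive") which.max(yi)
       else max(which(yi == max(yi)))
  list(cutoff = ths[i], se = roc$se[keep][i], sp = roc$sp[keep][i], yi = yi[i])
}

#' Confusion counts at a cut-off
#'
#' @inheritParams empirical_roc
#' @param cutoff Threshold from the score domain.
#' @return List of non-negative integers `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, cutoff,
                         orientation = c("higher_is_positive", "lower_is_positive")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  test_pos <- if (orientation == "higher_is_positive") scores >= cutoff
              else scores <= cutoff
  list(tp = sum(test_pos & labels), fp = sum(test_pos & !labels),
       tn = sum(!test_pos & !labels), fn = sum(!test_pos & labels))
}

#' Accuracy measures from confusion counts
#'
#' Sensitivity, specificity, predictive values and the Youden index on the
#' percent scale; likelihood ratios as ratios.  Undefined ratios (e.g. LRP
#' at perfect specificity) are returned as `Inf`/`NaN`, never as errors.
#'
#' @param counts List with `tp`, `fp`, `tn`, `fn` (see [confusion_at()]).
#' @return List with `se`, `sp`, `ppv`, `npv`, `yi` (percent, full
#'   precision), `lrp`, `lrn` (ratios).
#' @export
accuracy_measures <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn == 0 || tn + fp == 0) stop("both classes must be non-empty")
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  list(se = 100 * se, sp = 100 * sp,
       ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn),
       lrp = se / (1 - sp), lrn = (1 - se) / sp,
       yi = 100 * (se + sp - 1))
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Lower bound is the `alpha/2` quantile of Beta(k, n-k+1), upper the
#' `1-alpha/2` quantile of Beta(k+1, n-k); `k = 0` gives lower 0 and
#' `k = n` gives upper 1.
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials, `n >= 1`.
#' @param level Confidence level, default 0.95.
#' @return Numeric `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower, upper)
}

# Deterministic local RNG: run `expr` under `seed` and restore the caller's
# RNG state afterwards.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a label, so
# each (stratum, criterion, marker) gets its own independent stream.
derive_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 31 + v) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647) + 1L
}

#' Stratified bootstrap CI for the (re-maximized) Youden index
#'
#' Positives and negatives are resampled separately (so no replicate loses
#' a class) and the cut-off is re-optimized in each replicate, giving a CI
#' for the maximal Youden index.  Because threshold re-maximization makes
#' both the point estimate and every bootstrap replicate optimistic, the
#' plain percentile interval sits above the truth and undercovers; the
#' default interval is therefore Efron's bias-corrected (BC) percentile,
#' which shifts the quantiles by the bootstrap's median bias.  A
#' fixed-cutoff variant re-evaluates YI at a supplied threshold instead.
#'
#' @inheritParams empirical_roc
#' @param B Number of bootstrap replicates, >= 100.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param level Confidence level, default 0.95.
#' @param type `"bc"` (bias-corrected percentile, default) or
#'   `"percentile"`.
#' @param fixed_cutoff If non-NULL, evaluate YI at this cut-off in every
#'   replicate instead of re-optimizing.
#' @return Numeric `c(lower, upper)` on the percent scale.
#' @export
bootstrap_youden_ci <- function(scores, labels, orientation = "higher_is_positive",
                                B = 2000, seed = NULL, level = 0.95,
                                type = c("bc", "percentile"),
                                fixed_cutoff = NULL) {
  type <- match.arg(type)
  stopifnot(B >= 100)
  orientation <- match.arg(orientation, .ORIENTATIONS)
  labels <- as.logical(labels)
  .check_two_classes(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  n_pos <- length(pos); n_neg <- length(neg)
  yis <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      p <- pos[sample.int(n_pos, n_pos, replace = TRUE)]
      n <- neg[sample.int(n_neg, n_neg, replace = TRUE)]
      if (is.null(fixed_cutoff)) {
        .max_youden(p, n, orientation)$yi
      } else {
        cc <- confusion_at(c(p, n), c(rep(TRUE, n_pos), rep(FALSE, n_neg)),
                           fixed_cutoff, orientation)
        cc$tp / n_pos + cc$tn / n_neg - 1
      }
    }, numeric(1))
  })
  obs <- if (is.null(fixed_cutoff)) {
    .max_youden(pos, neg, orientation)$yi
  } else {
    cc <- confusion_at(scores, labels, fixed_cutoff, orientation)
    cc$tp / n_pos + cc$tn / n_neg - 1
  }
  100 * .boot_quantile_ci(yis, obs, level, type)
}

# Percentile or bias-corrected percentile interval from bootstrap draws.
.boot_quantile_ci <- function(draws, obs, level, type) {
  alpha <- 1 - level
  probs <- c(alpha / 2, 1 - alpha / 2)
  if (type == "bc") {
    # median-bias correction factor; degenerate bootstrap falls back to
    # the raw quantiles
    p0 <- mean(draws < obs) + 0.5 * mean(draws == obs)
    if (p0 > 0 && p0 < 1) {
      z0 <- stats::qnorm(p0)
      probs <- stats::pnorm(2 * z0 + stats::qnorm(probs))
    }
  }
  unname(stats::quantile(draws, probs, type = 6))
}

#' Paired-bootstrap test for two correlated AUCs
#'
#' Both markers are measured on the same subjects; each replicate draws one
#' stratified index set that drives both markers, the AUC difference is
#' recomputed, and the observed difference standardized by the bootstrap
#' standard deviation is referred to the standard normal (two-sided).
#'
#' @param scores_a,scores_b Numeric score vectors on the same subjects.
#' @param labels Logical disease labels; both classes required.
#' @param orientations Length-2 character vector of orientations for the
#'   two markers (recycled if length 1).
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `delta_auc` (AUC_a - AUC_b), `stat` (standardized
#'   difference), `p_value` (two-sided normal), `degenerate` (TRUE when the
#'   bootstrap sd is zero), `B`.
#' @export
compare_auc_paired_bootstrap <- function(scores_a, scores_b, labels,
                                         orientations = "higher_is_positive",
                                         B = 2000, seed = NULL) {
  labels <- as.logical(labels)
  .check_two_classes(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length")
  orientations <- rep(match.arg(orientations, .ORIENTATIONS, several.ok = TRUE),
                      length.out = 2)
  auc_a <- .auc_mw(scores_a, labels, orientations[1])
  auc_b <- .auc_mw(scores_b, labels, orientations[2])
  delta <- auc_a - auc_b

  ipos <- which(labels); ineg <- which(!labels)
  n_pos <- length(ipos); n_neg <- length(ineg)
  diffs <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(ipos[sample.int(n_pos, n_pos, replace = TRUE)],
               ineg[sample.int(n_neg, n_neg, replace = TRUE)])
      lb <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
      .auc_mw(scores_a[idx], lb, orientations[1]) -
        .auc_mw(scores_b[idx], lb, orientations[2])
    }, numeric(1))
  })
  s <- stats::sd(diffs)
  if (s == 0) {
    degenerate <- TRUE
    p <- if (delta == 0) 1 else 0
    stat <- if (delta == 0) 0 else Inf * sign(delta)
  } else {
    degenerate <- FALSE
    stat <- delta / s
    p <- 2 * stats::pnorm(-abs(stat))
  }
  list(delta_auc = delta, stat = stat, p_value = p,
       degenerate = degenerate, B = B)
}

#' Full accuracy report for one marker
#'
#' Composes ROC construction, AUC, Youden-optimal cut-off, confusion counts
#' and accuracy measures; attaches Clopper-Pearson CIs for Se (n = class of
#' diseased), Sp (non-diseased), PPV (test-positives) and NPV
#' (test-negatives), log-method CIs for the likelihood ratios, and
#' stratified bootstrap CIs for AUC (percentile) and the Youden index
#' (bias-corrected percentile, cut-off re-optimized per replicate; see
#' [bootstrap_youden_ci()]).
#'
#' @inheritParams empirical_roc
#' @param B Bootstrap replicates for the AUC and Youden CIs; `B = 0`
#'   skips the bootstrap (those CIs become NA).
#' @param seed Integer seed driving the bootstrap.
#' @param level Confidence level, default 0.95.
#' @return An object of class `"mets_accuracy"`: list with `cutoff`,
#'   `orientation`, `n_pos`, `n_neg`, `counts`, `auc`, `auc_ci`, and
#'   percent-scale `se`, `sp`, `ppv`, `npv`, `yi` with `*_ci` companions,
#'   plus `lrp`, `lrn` and their CIs.
#' @export
evaluate_marker <- function(scores, labels,
                            orientation = c("higher_is_positive", "lower_is_positive"),
                            B = 2000, seed = NULL, level = 0.95) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  roc <- empirical_roc(scores, labels, orientation)
  opt <- optimal_cutoff(roc)
  counts <- confusion_at(scores, labels, opt$cutoff, orientation)
  m <- accuracy_measures(counts)
  auc <- roc_auc(roc)
  z <- stats::qnorm(1 - (1 - level) / 2)

  cp <- function(k, n) 100 * clopper_pearson(k, n, level)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn

  lr_ci <- function(lr, a, m1, b, m2) {
    # log-normal CI for a likelihood ratio a/m1 over b/m2 (Simel's method)
    if (!is.finite(lr) || lr <= 0 || a == 0 || b == 0) return(c(NA_real_, NA_real_))
    se_log <- sqrt(1 / a - 1 / m1 + 1 / b - 1 / m2)
    exp(log(lr) + c(-1, 1) * z * se_log)
  }

  out <- list(
    orientation = orientation, n_pos = roc$n_pos, n_neg = roc$n_neg,
    cutoff = opt$cutoff, counts = counts,
    auc = auc, auc_ci = c(NA_real_, NA_real_),
    se = m$se, se_ci = cp(tp, tp + fn),
    sp = m$sp, sp_ci = cp(tn, tn + fp),
    ppv = m$ppv, ppv_ci = if (tp + fp > 0) cp(tp, tp + fp) else c(NA_real_, NA_real_),
    npv = m$npv, npv_ci = if (tn + fn > 0) cp(tn, tn + fn) else c(NA_real_, NA_real_),
    lrp = m$lrp, lrp_ci = lr_ci(m$lrp, tp, tp + fn, fp, fp + tn),
    lrn = m$lrn, lrn_ci = lr_ci(m$lrn, fn, tp + fn, tn, fp + tn),
    yi = m$yi, yi_ci = c(NA_real_, NA_real_)
  )

  if (B > 0) {
    pos <- scores[labels]; neg <- scores[!labels]
    n_pos <- length(pos); n_neg <- length(neg)
    boot <- .with_seed(seed, {
      vapply(seq_len(B), function(b) {
        p <- pos[sample.int(n_pos, n_pos, replace = TRUE)]
        n <- neg[sample.int(n_neg, n_neg, replace = TRUE)]
        sc <- c(p, n); lb <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
        c(.auc_mw(sc, lb, orientation), .max_youden(p, n, orientation)$yi)
      }, numeric(2))
    })
    out$auc_ci <- .boot_quantile_ci(boot[1, ], auc, level, "percentile")
    out$yi_ci <- 100 * .boot_quantile_ci(boot[2, ], opt$yi, level, "bc")
  }
  structure(out, class = "mets_accuracy")
}

#' @export
print.mets_accuracy <- function(x, ...) {
  dir <- if (x$orientation == "higher_is_positive") ">=" else "<="
  cat(sprintf("Cut-off %s %.2f | AUC %.3f (%.3f-%.3f)\n",
              dir, x$cutoff, x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("Se %.1f  Sp %.1f  PPV %.1f  NPV %.1f  LRP %.2f  LRN %.2f  YI %.1f\n",
              x$se, x$sp, x$ppv, x$npv, x$lrp, x$lrn, x$yi))
  invisible(x)
}
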
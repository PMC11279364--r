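---
title: "Evaluating surrogate metabolic-syndrome markers: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating surrogate metabolic-syndrome markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsdx)
```

# The problem

Metabolic syndrome (MetS) is defined by counting rules over five clinical
components; applying those rules requires waist circumference, blood
pressure and a fasting lipid/glucose panel.  Surrogate indices built from
subsets of these measurements (TyG, LAP, VAI, METS-IR, SPISE, …) are used
as inexpensive screening tests, and the scientific question is how well
each index discriminates rule-based MetS within sex and age strata.  This
package implements the full evaluation chain — cohort filtering, index
computation, rule-based diagnosis, and ROC-based accuracy analysis — as
tested, reusable code, exercised on synthetic cohorts.

# Cohort rules and their reading

Eligibility keeps adults (age ≥ 20) with fasting glucose in [70, 500]
mg/dL, triglycerides ≤ 1200 mg/dL and height ≥ 1.30 m.  The boundary
wording ("less than", "greater than") is strict, so the boundary values
themselves are kept.  Records missing any field consumed by a marker or a
criterion are eliminated.  Because a record can fail several rules, the
filter log attributes each record to the *first* failed rule in the fixed
order age → glucose → triglycerides → height → missingness; the counts
then partition the input exactly, which makes logs comparable across
runs.  The source material does not provide per-rule removal totals, so
no attempt is made to match any published flow-diagram attribution.

Age groups are closed–open on integer years, [20, 40), [40, 60),
[60, ∞), matching the printed labels with no gap or overlap.

# The ten indices

All formulas are evaluated at full precision with natural logarithms;
rounding is purely presentational.  Two indices need triglycerides and
HDL in mmol/L while survey biochemistry is in mg/dL; the standard molar
factors (88.57 for TG, 38.67 for cholesterol) are applied internally, and
a property test confirms conversion commutes with the index formulas.

Three choices deserve comment:

- **TyG** is implemented as `ln(TG·Glu)/2`, the form whose values sit
  around 4.6–4.9 and match the cut-offs this evaluation operates at — not
  the also-common `ln(TG·Glu/2)` (≈ 8.8 scale).
- **VAI for women** is the product of three factors, mirroring the men's
  formula and the original publication.  Some typeset sources show `+`
  between the women's factors; that variant is available verbatim behind
  `vai_women_as_printed = TRUE` so either behaviour can be reproduced,
  but the multiplicative form is the default because an additive mix of
  a ratio near 1, a TG factor near 2 and an HDL factor near 1 has neither
  the units nor the scale of the original index.
- **ABSI and BRI** have no formula in the source material; the canonical
  published definitions are used (waist and height in meters for ABSI).
  The resulting magnitudes (ABSI ≈ 0.07–0.08, BRI ≈ 4–6) agree with the
  cut-off scales published for these indices.

SPISE estimates insulin *sensitivity* and is the panel's only
negatively-oriented marker; the orientation registry drives every
downstream classification rule (`score ≤ t` positive instead of
`score ≥ t`), so AUCs are always reported above 0.5 for informative
markers.  VAT = exp(METS-VF) is a strictly monotone transform, so the two
indices produce identical ROC curves, AUCs and Youden rows — a useful
end-to-end invariant that the tests assert exactly.

# Diagnosis rules

ATP III and IDF are implemented exactly as printed: HDL thresholds are
strict (`<`), all others inclusive (`≥`); "BP ≥ 130/85" means SBP ≥ 130
*or* DBP ≥ 85; prior diagnoses satisfy the glucose and blood-pressure
components; triglyceride-lowering treatment satisfies the TG component
under IDF only.  Published variants that add treatment clauses to the
ATP III TG component or the HDL components exist, but the printed
definition used here has none, and the open question of whether the
original analysis used them is resolved by following the printed text.

# Accuracy machinery

The empirical ROC curve classifies at every unique observed score plus
±∞ sentinels, guaranteeing the (Se, Sp) endpoints (1, 0) and (0, 1).
The trapezoidal AUC over (1 − Sp, Se) equals the Mann–Whitney
concordance probability with ties counted ½ — asserted against a
brute-force all-pairs oracle.  The reported cut-off is always an observed
value (published cut-offs look like data values, not midpoints), chosen
to maximize J = Se + Sp − 1; ties are broken toward the smallest
threshold for positively-oriented markers (maximal sensitivity among
ties) and the largest for SPISE, a deterministic rule the source is
silent on.

Confidence intervals:

- **Se, Sp, PPV, NPV**: exact Clopper–Pearson with n equal to the
  relevant denominator (diseased, non-diseased, test-positives,
  test-negatives respectively).
- **Likelihood ratios**: standard log-normal (Simel) intervals.
- **AUC**: stratified bootstrap (positives and negatives resampled
  separately), percentile interval.
- **Youden index**: the same stratified bootstrap with the cut-off
  *re-optimized in every replicate*, so the interval is for the maximal
  J.  Re-maximization makes both the point estimate and each replicate
  optimistic: on a binormal design (separation 1.5 SD, 500 per class)
  the estimator is biased up by about 1.2 points and the plain percentile
  interval covers the true maximal J only ~87–88% of the time.  The
  default interval is therefore Efron's bias-corrected (BC) percentile,
  which shifts the quantile positions by the bootstrap's median bias and
  restores coverage to within a few points of nominal (~92–95% on the
  same design).  `type = "percentile"` and a fixed-cutoff variant remain
  available.
- **Correlated AUCs**: a paired stratified bootstrap — one resampled
  index set drives both markers per replicate — standardizing the
  observed AUC difference by the bootstrap standard deviation and
  referring it to the standard normal, two-sided.  A degenerate bootstrap
  (zero sd) with a zero observed difference yields p = 1; with a nonzero
  difference it is flagged and reported as p = 0.

Bootstrap defaults: B = 2000 replicates, stratified by class, a seed is
mandatory whenever the bootstrap runs.  Per-(stratum, criterion, marker)
sub-seeds are derived by hashing labels against the master seed, so
results are independent of evaluation order and reruns are byte-identical.

No multiplicity adjustment is applied across the marker family, and AUC
comparisons default to the three pairs among the top three markers per
stratum, matching the usual reporting pattern; `pairs = "all"` overrides.

# The synthetic cohort generator

`generate_cohort()` emulates the features of a national nutrition survey
that this analysis actually consumes:

- **Marginals**: per-sex location/scale for height, BMI, waist, HDL,
  blood pressures and total cholesterol (truncated normal), and
  log-normal triglycerides and glucose (their published quartiles are
  strongly right-skewed).  Locations are set so a default cohort's
  medians land within a few percent of the published population medians
  (BMI 28.4 kg/m², WC 95.8 cm, TG 168 mg/dL, Glu 92 mg/dL, HDL
  43 mg/dL) — the ±10% calibration the tests assert.
- **Dependence**: a Gaussian copula for residual correlations
  (waist–BMI, SBP–DBP, TG–HDL, …) whose values are engineering choices,
  not survey estimates — no correlation matrix is published.
- **Latent risk burden**: one half-normal score
  `latent_risk_sd · |N(0,1)|`, centered on the unit half-normal median,
  with loadings that push waist, BMI, TG, glucose and blood pressure up
  and HDL down.  A *one-sided* burden was a deliberate correction: a
  zero-mean Gaussian factor makes IDF prevalence *fall* as the factor
  grows, because the IDF waist gate is satisfied by ~90% of women and
  the expected count of the remaining four components sits right at the
  ≥ 2 threshold, so added dispersion removes mass from
  {gate AND ≥ 2-of-4}.  With a stochastically-increasing burden and
  disease-pointing loadings, every component-exceedance probability is
  non-decreasing in `latent_risk_sd`, hence prevalence is monotone under
  *any* counting rule — the property the tests check on a 3-point grid.
  The centering keeps default medians calibrated.
- **Flags**: diagnosis/treatment indicators drawn conditional on the
  matching component (P = 0.3 if exceeded, 0.02 otherwise — plausible
  defaults; no flag prevalences are published).
- **Weight** is derived as BMI · height², so the BMI consistency
  invariant holds by construction rather than within a tolerance.
- **Reproducibility**: every variable draws from its own seed-derived
  stream and the copula mixing matrix is upper-triangular in a fixed
  variable order, so appending a new field never perturbs existing
  draws.  Values are clamped inside the eligibility window by default so
  filter tests introduce exclusions explicitly.

What a green test on synthetic data does *not* establish: agreement with
any real survey's joint distribution, survey-design effects (weights,
clustering), measurement error, or the published point estimates — those
were computed on external microdata and are out of reach by design.  The
generator establishes that the machinery is correct and that the
qualitative regime (MetS prevalence 40–60%, lipid-based markers with
AUC > 0.75) reproduces.

# Numerical conventions and degenerate inputs

- Proportions are carried at full precision; percentages (1 dp), LRs
  (2 dp) and AUC (3 dp) are formatting choices in the rendering layer.
- Undefined ratios (LR+ at Sp = 1, PPV with no test-positives) are
  reported as `Inf`/`NA`, never raised as errors.
- Single-class strata are reported as non-evaluable; the run continues.
- `k = 0` and `k = n` Clopper–Pearson bounds are exactly 0 and 1.
- Youden CIs of constant scores collapse to (0, 0).

# Known limitations

- The per-rule filter counts cannot be validated against the published
  flow diagram (attribution is unpublished); only the partition property
  is guaranteed.
- The BC bootstrap restores Youden-CI coverage to within a few points of
  nominal but not exactly to it; at very small strata (< ~100 per class)
  re-maximization bias grows and the interval should be read
  conservatively.
- The correlated-AUC test uses a normal approximation on the
  standardized bootstrap difference; no DeLong analytic variance is
  provided.
- Exact parity with any published confidence intervals is not attempted
  (the published tables themselves contain internal inconsistencies,
  e.g. a specificity CI that differs between a table and the text).
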
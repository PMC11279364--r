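# Frozen expected values were computed independently (direct arithmetic /
# high-precision evaluation) before the implementation existed.

test_that("unit conversion uses the standard molar factors", {
  expect_equal(mgdl_to_mmol(177.14, "triglycerides"), 2.0000, tolerance = 1e-4)
  expect_equal(mgdl_to_mmol(38.67, "cholesterol"), 1.0000)
  expect_error(mgdl_to_mmol(0, "triglycerides"), "positive")
  expect_error(mgdl_to_mmol(100, "glucose"))
})

test_that("index formulas reproduce frozen values", {
  expect_equal(spise(1, 1, 1), 600)                      # unit powers
  expect_equal(spise(50, 100, 25), 6.637, tolerance = 1e-3)
  expect_equal(mets_ir(100, 150, 30, 40), 47.640, tolerance = 1e-4)
  expect_equal(mets_ir(92, 168, 28.4, 43), 44.275, tolerance = 1e-3)
  expect_equal(tg_hdl(150, 50), 3.0)
  expect_equal(tg_hdl(168, 43), 3.907, tolerance = 1e-3)
  expect_equal(tyg(1, 1), 0)
  expect_equal(tyg(150, 100), 4.8079, tolerance = 1e-4)
  expect_equal(tyg(117, 92), 4.642, tolerance = 1e-3)
  expect_equal(lap("male", 65, 123), 0)
  expect_equal(lap("female", 58, 321), 0)
  expect_equal(lap("male", 100, 177.14), 70.00, tolerance = 1e-3)
  expect_equal(vai("male", 95, 28, 2.0 * 88.57, 1.0 * 38.67), 2.618,
               tolerance = 1e-3)
  expect_equal(mets_vf(45, 0.6, "male", 50), 7.284, tolerance = 3e-4)
  expect_equal(mets_vf(45, 0.6, "female", 50),
               mets_vf(45, 0.6, "male", 50) - 0.319)
  expect_equal(mets_vf(45, 1, "male", 50),                # WHtR term vanishes at 1
               4.466 + 0.011 * log(45)^3 + 0.319 + 0.594 * log(50))
  expect_equal(vat(0), 1)
  expect_equal(vat(7.284), 1456.4, tolerance = 3 / 1456.4)
  expect_equal(absi(100, 1, 1), 1.0)
  expect_equal(absi(95.8, 28.4, 1.62), 0.0809, tolerance = 0.0003 / 0.0809)
  expect_equal(bri(95.8, 1.62), 5.23, tolerance = 0.02 / 5.23)
  expect_equal(bri(1e-9, 1.62), 364.2 - 365.5, tolerance = 1e-6)
})

test_that("formula contracts reject invalid inputs", {
  expect_error(mets_ir(100, 150, 30, 1), "hdl")
  expect_error(spise(-1, 100, 25), "positive")
  expect_error(mets_vf(45, 0.6, "male", 19), "age")
  expect_error(vat(Inf), "finite")
  expect_error(bri(600, 1.62), "ellipse")   # wc/(pi*h) >= 1
})

test_that("VAI sex-specific factors: each factor 1 gives 1; women's printed form differs", {
  # men: wc = 1.88*bmi + 39.68, tg = 1.03 mmol/L, hdl = 1.31 mmol/L
  bmi <- 27
  expect_equal(vai("male", 1.88 * bmi + 39.68, bmi, 1.03 * 88.57, 1.31 * 38.67), 1)
  # women multiplicative default: wc = 1.89*bmi + 36.58, tg = 0.81, hdl = 1.52
  expect_equal(vai("female", 1.89 * bmi + 36.58, bmi, 0.81 * 88.57, 1.52 * 38.67), 1)
  # verbatim (typeset) women's form sums the three unit factors
  expect_equal(vai("female", 1.89 * bmi + 36.58, bmi, 0.81 * 88.57, 1.52 * 38.67,
                   women_as_printed = TRUE), 3)
  # men unaffected by the switch
  expect_equal(vai("male", 95, 28, 180, 40, women_as_printed = TRUE),
               vai("male", 95, 28, 180, 40))
})

test_that("scale contract: mmol conversion commutes for LAP and VAI", {
  set.seed(21)
  n <- 50
  sex <- sample(c("male", "female"), n, TRUE)
  wc <- runif(n, 70, 120); bmi <- runif(n, 20, 38)
  tg <- runif(n, 60, 400); hdl <- runif(n, 25, 70)
  lap_direct <- lap(sex, wc, tg)
  off <- ifelse(sex == "male", 65, 58)
  expect_equal(lap_direct, (wc - off) * mgdl_to_mmol(tg, "triglycerides"))
  vai_direct <- vai(sex, wc, bmi, tg, hdl)
  tgm <- tg / 88.57; hdlm <- hdl / 38.67
  f1 <- ifelse(sex == "male", wc / (1.88 * bmi + 39.68), wc / (1.89 * bmi + 36.58))
  f2 <- ifelse(sex == "male", tgm / 1.03, tgm / 0.81)
  f3 <- ifelse(sex == "male", 1.31 / hdlm, 1.52 / hdlm)
  expect_equal(vai_direct, f1 * f2 * f3, tolerance = 1e-12)
})

test_that("all formulas agree with an independent per-row evaluation", {
  set.seed(33)
  n <- 200
  sex <- sample(c("male", "female"), n, TRUE)
  age <- sample(20:85, n, TRUE)
  h <- runif(n, 1.35, 1.95); bmi <- runif(n, 17, 42)
  wc <- runif(n, 60, 130); hdl <- runif(n, 20, 80)
  tg <- runif(n, 50, 800); glu <- runif(n, 70, 300)
  whtr <- wc / (100 * h)
  # scalar re-derivation straight from the printed formulas
  for (i in sample(n, 25)) {
    mir <- log(2 * glu[i] + tg[i]) * bmi[i] / log(hdl[i])
    expect_equal(mets_ir(glu[i], tg[i], bmi[i], hdl[i]), mir, tolerance = 1e-9)
    mvf <- 4.466 + 0.011 * log(mir)^3 + 3.239 * log(whtr[i])^3 +
      0.319 * (sex[i] == "male") + 0.594 * log(age[i])
    expect_equal(mets_vf(mir, whtr[i], sex[i], age[i]), mvf, tolerance = 1e-9)
    expect_equal(vat(mvf), exp(mvf), tolerance = 1e-9)
    expect_equal(spise(hdl[i], tg[i], bmi[i]),
                 600 * hdl[i]^0.185 / (tg[i]^0.2 * bmi[i]^1.338), tolerance = 1e-9)
    expect_equal(tyg(tg[i], glu[i]), log(tg[i] * glu[i]) / 2, tolerance = 1e-9)
    expect_equal(absi(wc[i], bmi[i], h[i]),
                 (wc[i] / 100) / (bmi[i]^(2 / 3) * sqrt(h[i])), tolerance = 1e-9)
    expect_equal(bri(wc[i], h[i]),
                 364.2 - 365.5 * sqrt(1 - ((wc[i] / 100) / (2 * pi))^2 / (0.5 * h[i])^2),
                 tolerance = 1e-9)
  }
})

test_that("compute_panel is consistent and monotone in triglycerides", {
  co <- apply_eligibility(generate_cohort(cohort_spec(n = 300, seed = 8)))$kept
  pan <- compute_panel(co)
  expect_setequal(setdiff(names(pan), "id"), marker_ids())
  expect_equal(pan$VAT, exp(pan$METS_VF))
  expect_equal(sum(marker_orientations() == "lower_is_positive"), 1)
  expect_equal(names(which(marker_orientations() == "lower_is_positive")), "SPISE")
  # raising tg strictly raises TYG, LAP, TG_HDL, VAI
  co2 <- co; co2$tg_mgdl <- co2$tg_mgdl + 25
  pan2 <- compute_panel(co2)
  for (mk in c("TYG", "LAP", "TG_HDL", "VAI"))
    expect_true(all(pan2[[mk]] > pan[[mk]]), label = mk)
  # doubling BMI strictly decreases SPISE
  co3 <- co; co3$bmi <- co3$bmi * 2
  expect_true(all(compute_panel(co3)$SPISE < pan$SPISE))
})
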
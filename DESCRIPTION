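Package: metsdx
Title: Surrogate Insulin-Resistance and Obesity Indices for Metabolic
    Syndrome Diagnosis
Version: 0.1.0
Authors@R:
    person("ENSANUT", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes ten surrogate insulin-resistance and obesity indices
    (SPISE, METS-IR, TG/HDL, TyG, LAP, VAI, METS-VF, VAT, ABSI, BRI),
    applies rule-based metabolic-syndrome diagnosis under the ATP III and
    IDF definitions, and evaluates each index as a diagnostic test via
    empirical ROC curves, Youden-index cut-off selection, exact
    Clopper-Pearson confidence intervals, bootstrap Youden/AUC intervals,
    and a paired-bootstrap test for correlated AUCs.  Includes a synthetic
    survey-cohort generator with a latent metabolic-risk factor and a
    Gaussian copula so the full pipeline is testable without external
    microdata, plus a command-line interface orchestrating the
    filter/markers/labels/evaluate/report stages stratified by sex and
    age group.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
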
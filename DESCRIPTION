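Package: earlytnf
Title: Outcome Derivation and Causal Effect Estimation for Early Anti-TNF
    Therapy in Paediatric Crohn's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Rule-based derivation of sustained steroid-free clinical
    outcomes from longitudinal paediatric Crohn's disease records
    (disease-activity and endoscopy categorisation, predictors of poor
    outcome, early anti-TNF exposure, treatment-intensification events),
    together with causal effect estimation by ridge-penalised logistic
    regression with model-based standardisation (g-computation), bootstrap
    variance, and multiple imputation by chained equations pooled with
    Rubin's rules. Includes a synthetic longitudinal cohort generator with
    severity-driven confounding by indication and a Monte-Carlo
    potential-outcomes oracle for parameter-recovery testing, LMS growth
    Z-scores, and descriptive reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    nnet,
    Rcpp,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
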
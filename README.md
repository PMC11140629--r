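# earlytnf

Outcome derivation and causal effect estimation for **early anti-TNFα
therapy in newly diagnosed paediatric Crohn's disease**.

Observational inception cohorts are the only practical way to study whether
starting infliximab or adalimumab within 90 days of diagnosis improves
sustained, steroid-free disease control — but treatment is assigned by
indication: sicker children are treated earlier. This package, aimed at
clinical epidemiologists and biostatisticians working with longitudinal
paediatric IBD data, implements the full analysis pipeline:

* **Rule-based outcome derivation** from raw records: wPCDAI/PGA activity
  categories, SES-CD endoscopic categories, predictors of poor outcome
  (POPOs), early anti-TNF exposure, arm-specific treatment-intensification
  events, and the tri-state (true / false / not-evaluable) outcome family —
  SSFR\*, SSFMI\* and friends — where, e.g., SSFR\* means clinical remission at
  every scheduled visit from month 3 to the horizon, no corticosteroid
  course after the induction window, and no treatment intensification.
* **Causal estimation** by ridge-penalised logistic regression
  (log-likelihood − λ‖β‖²) with **regression standardisation**
  (g-computation): with fitted risks r(a, x), the marginal risks are
  p̄ₐ = n⁻¹ Σᵢ r(a, xᵢ) and the estimands are RR = p̄₁/p̄₀,
  OR = odds(p̄₁)/odds(p̄₀), RD = p̄₁ − p̄₀. Variance by patient-level
  bootstrap within each imputed dataset; missing covariates handled by
  chained-equations multiple imputation; results pooled with Rubin's rules
  (Barnard–Rubin degrees of freedom); risk-subgroup (activity / POPO)
  analyses included.
* A **synthetic cohort generator** whose single latent severity process
  drives activity, biomarkers, POPOs *and* treatment assignment, so
  confounding by indication is real; it draws both potential outcomes and
  writes patient records that the outcome engine decodes back to exactly
  the generated labels — plus a Monte-Carlo oracle for the true marginal
  effects, enabling honest calibration and parameter-recovery tests.

## Worked example

```r
library(earlytnf)

cfg    <- sim_config(n = 331, seed = 42)      # study-scale synthetic cohort
cohort <- simulate_cohort(cfg)                # records + missingness + truth

flags <- derive_outcomes(cohort, horizon_month = 12)
outcome_table(flags, c("ssfr_star", "ssfmi_star"))[, c(1, 4, 7, 11)]
#> # A tibble: 2 × 4
#>   outcome    pct_early pct_noearly     p_value
#>   <chr>          <dbl>       <dbl>       <dbl>
#> 1 ssfr_star         25          16 0.0588
#> 2 ssfmi_star        62          32 0.000000288

res <- estimate_effect(cohort, outcome = "ssfr_star",
                       m = 30, n_reps = 1000, seed = 42)
res$estimates[res$estimates$scale == "rr",
              c("scale", "estimate", "ci_low", "ci_high", "p_value")]
#> # A tibble: 1 × 5
#>   scale estimate ci_low ci_high p_value
#>   <chr>    <dbl>  <dbl>   <dbl>   <dbl>
#> 1 rr        1.89   1.19    2.99 0.00700

true_marginal_effects(cfg)$true_marginal_rr   # the oracle the estimator targets
#> [1] 2.316
```

The raw arm difference (25% vs 16% in sustained steroid-free remission
without intensification) is a *confounded* contrast; the pooled standardised
RR (1.89, 95% CI 1.19–2.99 in this draw) estimates the marginal causal
effect, whose generator truth is 2.32. Cohorts can equally be read
from four CSV tables (`read_cohort()`) with the documented schema, and the
whole pipeline is scriptable from a YAML config via `run_pipeline()` — see
`inst/extdata/demo_config.yaml`.

## Package tour

| Area | Functions |
| --- | --- |
| Cohort container & I/O | `cd_cohort()`, `read_cohort()`, `write_cohort()`, `analysis_set()` |
| Classifiers | `categorize_activity()`, `categorize_sescd()`, `categorize_mini()`, `classify_exposure()`, `derive_popos()` |
| Outcome engine | `steroid_free()`, `detect_intensification()`, `sustained_status()`, `derive_outcomes()`, `three_month_response()`, `status_at_3m()`, `conditional_subset()` |
| Growth & HRQOL | `lms_zscore()`, `visit_zscores()`, `delta_scores()` |
| Synthetic data | `sim_config()`, `simulate_cohort()`, `draw_analysis_sample()`, `inject_missingness()`, `true_marginal_effects()` |
| Imputation | `chained_impute()`, `complete_all()`, `pool_rubin()` |
| Estimation | `fit_ridge_logistic()`, `standardize()`, `bootstrap_effect()`, `estimate_pooled()`, `subgroup_estimates()`, `estimate_effect()` |
| Reporting | `compare_groups()`, `outcome_table()`, `run_pipeline()` |

The methods vignette (`vignettes/methods.Rmd`) documents the model, its
assumptions, every tunable threshold, and the design decisions in detail.
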
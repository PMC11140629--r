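---
title: "Methods: outcome derivation and causal estimation for early anti-TNF in paediatric Crohn's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outcome derivation and causal estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlytnf)
```

## The scientific question

In newly diagnosed paediatric Crohn's disease, clinicians must decide whether
to start an anti-TNF&alpha; biologic (infliximab or adalimumab) early — within
90 days of diagnosis, upfront or as early intensification — or to follow a
conventional step-up strategy. Because the decision is driven by disease
severity, observational comparisons suffer confounding by indication: the
treated children are systematically sicker. This package implements the full
analysis pipeline for estimating the marginal causal effect of early anti-TNF
on sustained, steroid-free clinical outcomes from longitudinal cohort
records, together with a synthetic cohort generator that makes the pipeline
testable against known truth.

## Outcome derivation

All outcomes are derived from raw records (visits, therapy courses, surgery
events) by deterministic rules, with three-valued logic throughout: a flag is
`TRUE`, `FALSE`, or `NA` ("not evaluable"), and a definite failure anywhere
beats missingness elsewhere. This mirrors how varying denominators arise in
clinical outcome tables: each outcome's denominator is the set of patients
for whom it can be decided.

* **Disease activity** is the wPCDAI (0–127.5) categorised as
  remission (< 12.5), mild (12.5–40), moderate (> 40–57.5) or severe
  (> 57.5), falling back to the four-level physician's global assessment
  when the wPCDAI is missing. The exact four-group cut points are exposed in
  `analysis_thresholds()` because banding conventions differ between
  reports; whether the moderate band is closed at 57.5 is a convention, and
  we use a closed upper bound.
* **Sustained** statuses ("continuous remission from month 3 to the
  horizon") are operationalised as the per-visit condition holding at every
  *scheduled* protocol visit in the window (months 3, 6, 12, and 18/24 for
  the 2-year horizon). Between-visit relapses are unobservable at protocol
  resolution and are deliberately ignored.
* **Steroid-freedom** over a window `(t0, t1]` means no corticosteroid
  course overlaps the half-open interval; a course ending exactly at `t0`
  does not violate it. The default window starts the day after the 90-day
  early-therapy window, so induction steroids in the first three months do
  not disqualify a patient from sustained steroid-free remission.
* **Treatment intensification** is arm-specific: escalation to a
  second-line biologic (ustekinumab/vedolizumab) for early-anti-TNF
  patients, escalation to *any* biologic after day 90 for the others, or
  IBD-related luminal surgery in either arm. In-class anti-TNF switches and
  dose intensification never count. An escalation on the horizon day itself
  counts (the boundary is not otherwise specified by convention; we document
  the inclusive choice). A biologic started inside the early window by a
  patient classified as *not* early is impossible by construction of the
  arms, and the engine raises a data-consistency error rather than silently
  reclassifying.
* The **90-day window is closed** (`start_day <= 90` is early), and
  "upfront" means the anti-TNF was the chronologically first
  induction-class therapy; immunomodulator co-medication does not void
  upfront status, since combination therapy is standard practice.
* **Predictors of poor outcome (POPOs)**: perianal disease; deep colonic
  ulcers (any colonic SES-CD ulcer sub-score large/very large); extensive
  disease (L3 plus L4a/L4b); growth delay (height-for-age Z < −1.5,
  strictly); complicated disease (B2/B3, or B1 with narrowing without
  prestenotic dilatation). Missing perianal and complicated-disease flags
  are deterministically assumed negative; the other three stay missing and
  are left to multiple imputation. A single perianal flag serves both as
  Paris modifier and POPO.

## Growth Z-scores

Height-for-age and BMI-for-age Z-scores use the LMS method,
`z = ((x/M)^L − 1)/(L·S)` with the log-limit at `L = 0`. Reference `(L, M,
S)` rows are interpolated linearly in age between bracketing rows; at
monthly reference resolution the difference from nearest-row lookup is
negligible. The package ships a *synthetic* reference table purely so
examples and tests run without a download; any real growth-standard table in
the same CSV schema can be substituted, and the module is deliberately
agnostic about which reference (under-5 growth standards vs 5–19 reference)
is appropriate for a mostly school-age cohort.

## Missing data

Covariates entering the outcome model are completed by multiple imputation
by chained equations: predictive-mean matching (k = 5 donors, a standard
default) for continuous variables, Bayesian logistic draws for binary ones,
polytomous regression for categoricals (class probabilities only — the
coefficient draw is omitted for the rare multi-level auxiliaries, a known
simplification). The imputation model includes auxiliary predictors (wPCDAI,
FCP, SES-CD, ESR) beyond the model covariates. Faecal calprotectin, with
over half its values missing, is never a model covariate but is allowed to
help impute the covariates. Defaults are m = 30 imputations and 10 cycles;
per-imputation chains run on independent substreams of one master seed.
Convergence is assessed by exported chain-mean/SD traces; a warning fires
when the chain mean drifts more than 0.5 SD between the final two cycles.
Pooling follows Rubin's rules with Barnard–Rubin small-sample degrees of
freedom; ratio effects are pooled on the log scale and exponentiated, since
log-ratios are the approximately normal quantity.

## Causal estimation

The outcome model is a logistic regression of the 1-year outcome on
treatment plus age, sex, moderate-to-severe activity, CRP and the five
POPOs, maximised with a ridge penalty `λ Σ β²` — equivalently a mean-zero
Gaussian prior — which keeps estimates finite under near-separation and
lets a relatively rich covariate set into a modest sample. Choices that the
convention leaves open, and how we resolved them:

* **λ default**: `λ = 1/(2σ²)` with prior SD σ = 2 on standardised
  coefficients (λ = 0.125) — weakly informative; configurable.
* **The treatment coefficient is penalised** like the others by default;
  `penalize_treatment = FALSE` is exposed because it changes the shrinkage
  behaviour of the estimand — use deliberately.
* Continuous covariates are standardised to unit variance before
  penalisation and coefficients reported back on the original scale. CRP
  enters untransformed by default (a log transform is a one-line config).
* At `λ = 0` the fit reduces to maximum likelihood and refuses to return
  under separation instead of emitting garbage.

**Regression standardisation (g-computation)** turns the conditional fit
into marginal contrasts: predict every patient's risk under treatment-for-all
and control-for-all, average, and form RR = p̄₁/p̄₀, OR, and the risk
difference. Under no unmeasured confounding these are the contrasts an
arm-randomised trial would estimate. Algebraically OR = RR·(1−p̄₀)/(1−p̄₁),
so both always sit on the same side of 1 with |log OR| ≥ |log RR| — an
invariant the test suite asserts on every estimate.

**Variance** comes from a patient-level nonparametric bootstrap (default
1000 replicates) *within* each imputed dataset — the stated order is impute,
then bootstrap within — refitting the penalised model (λ fixed across
replicates; warm-started from the full-data fit, reusing its covariate
scaling) and re-standardising within each resample. Per-imputation points
and bootstrap variances are pooled with Rubin's rules on the log scale;
intervals are Wald-type on the pooled scale (variance-based, not
percentile), consistent with pooling by combining estimates and their
variances.

**Subgroups**: the risk-stratified analyses re-run the whole machinery
within strata defined by baseline activity (mild/inactive vs
moderate/severe) or by POPO carriage, using the milder sustained outcome to
preserve effective sample size. Stratum-constant covariates (the stratifier
itself; the POPO flags in the no-POPO stratum) are dropped from the
within-stratum model. Strata are formed within each imputed dataset, so
membership can differ across imputations when the stratifier was imputed.

## The synthetic cohort generator

The generator's defaults *are* the study conditions the pipeline is tested
under: 331 patients, ~41% treated early, ~62% male, ~67% moderate-to-severe
activity, heavy (>50%) faecal-calprotectin missingness, ~30% missing
endoscopy. One latent severity variable drives disease activity, CRP, FCP,
the POPO prevalences *and* the propensity to receive early anti-TNF, so the
confounders genuinely confound — under the default mechanism the crude RR
(≈2.0) understates the true marginal RR (≈2.3), the signature of
confounding by indication.

Potential outcomes are generated under consistency and no interference: the
primary outcome (sustained steroid-free remission without intensification)
follows a logistic model whose treatment coefficient (default log 3.1, a
plausible scale for an adjusted conditional odds ratio in this setting) is
the true conditional effect; intercepts are calibrated by simulation so the
marginal treated fraction and the untreated outcome risk hit their targets
(0.41 and 0.14). Patients failing the primary outcome are assigned an
arm-specific *failure mode* — mild-only activity excursions, moderate/severe
excursions, a steroid course inside the steroid-free window, or treatment
intensification — chosen so the milder sustained outcome lands near its
target arm rates (≈69% vs ≈33%). Records (visit trajectories, therapy courses, escalations,
surgeries) are then written so that the outcome engine decodes them back to
exactly the drawn labels; the fidelity test asserts 100% label agreement on
missingness-free cohorts, at both horizons. `draw_analysis_sample()` is the
fast path that skips record construction; because of the exact-decoding
property, estimator experiments on it are equivalent to running the full
record pipeline.

The trajectory model (activity decay, within-arm persistence at months
18/24, visit-level CRP/FCP conditional on activity) is an artifact of this
package — no within-arm longitudinal model is part of the source material —
and is labelled as such; it exists to make the records realistic and
decodable, not to claim clinical realism of trajectories. Monte-Carlo truth
comes from `true_marginal_effects()`, which brute-forces the potential-outcome
means over the covariate distribution (closed form per draw, so the only MC
error is covariate sampling).

What the generator does *not* emulate: clustering by centre, visit-window
violations, measurement error in the wPCDAI, informative dropout, and
not-missing-at-random endoscopy (endoscopy is deleted as a block, but
independently of severity). Passing recovery tests therefore demonstrates
the estimator works under its stated assumptions, not that those assumptions
hold in any real cohort.

## Numerical choices and problem sizes

* IRLS with step-halving and a gradient-based convergence check; bootstrap
  refits are warm-started and capped at 30 iterations.
* PMM uses a stabilising `1e-5` proportional ridge on the cross-product
  matrix; logistic imputation draws use a `1e-4` ridge to survive separation
  in small strata.
* The calibration experiments in the test suite use scaled-down sizes
  chosen to keep the whole suite fast while leaving the statistical
  conclusions clear: type-I error of the pooled test over 200 replicates
  (n = 1000, m = 5, 200 bootstrap replicates) must land in [0.02, 0.09];
  coverage of the oracle truth over 100 replicates (n = 2000) in [88%, 99%];
  coverage of pooled means under MCAR over 200 small replicates in
  [90%, 98%].
* `scripts/acceptance.R` reruns the full study-scale pipeline (n = 331,
  m = 30, 1000 bootstrap replicates) from a single seed.

## Known limitations

* The imputation engine is a purpose-built fully-conditional-specification
  implementation, not a general framework: no passive imputation, no
  multilevel structure (centres are not modelled in the estimator either),
  and the polytomous method does not draw coefficients.
* Wald intervals on the log scale can undercover for very rare outcomes in
  small strata; the subgroup machinery warns below 25 subjects per stratum.
* Time-to-event analyses of escalation are out of scope; the engine reports
  event indicators at fixed horizons only.
* The MINI-index mild vs moderate-severe boundary above the validated
  mucosal-healing cut (< 3) is an unvalidated default (8) and is flagged as
  such at the API level.
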
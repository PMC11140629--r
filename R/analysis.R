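#' Assemble the patient-level analysis dataset
#'
#' Joins baseline covariates, derived exposure, predictors of poor outcome
#' and the outcome flags at a horizon into the one-row-per-patient frame the
#' imputation and estimation steps consume. The model confounders are age at
#' diagnosis, sex, moderate-to-severe baseline activity, CRP and the five
#' POPO flags (perianal and complicated disease already negative-filled by
#' [derive_popos()]); auxiliaries carried for the imputation model are the
#' baseline wPCDAI, faecal calprotectin, SES-CD total, ESR, disease location
#' and upper-GI involvement. Patients flagged as pre-1-year dropouts are
#' excluded.
#'
#' @param cohort a [cd_cohort].
#' @param outcome which outcome flag becomes the `outcome` column.
#' @param horizon_month outcome horizon (12 or 24).
#' @param thresholds an [analysis_thresholds()] object.
#' @param ref_table LMS reference for the growth-delay POPO.
#' @param keep_unevaluable keep rows whose outcome is not evaluable
#'   (default `FALSE`: the analysis denominator is the evaluable set).
#' @return a tibble; `attr(, "outcomes")` holds the full outcome-flag table.
#' @export
build_analysis_data <- function(cohort, outcome = "ssfr_star",
                                horizon_month = 12,
                                thresholds = analysis_thresholds(),
                                ref_table = lms_reference_synthetic(),
                                keep_unevaluable = FALSE) {
  cohort <- analysis_set(cohort)
  exposure <- classify_exposure(cohort, thresholds)
  popos <- derive_popos(cohort, thresholds, ref_table = ref_table)
  flags <- derive_outcomes(cohort, horizon_month = horizon_month,
                           exposure = exposure, thresholds = thresholds)
  stopifnot(outcome %in% names(flags))
  b <- cohort$baseline
  act <- categorize_activity(b$wpcdai, b$pga, thresholds$wpcdai_cuts)
  dat <- tibble(
    id = b$id,
    early_antitnf = exposure$early_antitnf[match(b$id, exposure$id)],
    outcome = flags[[outcome]][match(b$id, flags$id)],
    age_years = b$age_years,
    sex = b$sex,
    moderate_severe_activity = is_moderate_severe(act),
    crp = b$crp,
    perianal = popos$perianal[match(b$id, popos$id)],
    deep_colonic_ulcers = popos$deep_colonic_ulcers[match(b$id, popos$id)],
    extensive_disease = popos$extensive_disease[match(b$id, popos$id)],
    growth_delay = popos$growth_delay[match(b$id, popos$id)],
    complicated_disease = popos$complicated_disease[match(b$id, popos$id)],
    any_popo = popos$any_popo[match(b$id, popos$id)],
    wpcdai = b$wpcdai,
    fcp = b$fcp,
    esr = b$esr,
    sescd_total = b$sescd_total,
    paris_location = b$paris_location,
    upper_gi = b$upper_gi
  )
  if (!keep_unevaluable) dat <- dat[!is.na(dat$outcome), , drop = FALSE]
  attr(dat, "outcomes") <- flags
  dat
}

#' End-to-end causal effect of early anti-TNF on an outcome
#'
#' Convenience wrapper running the full estimation pipeline on a cohort:
#' build the analysis dataset, multiply impute the incomplete covariates,
#' fit the ridge-penalised outcome model, standardise to marginal risks,
#' bootstrap within each completed dataset and pool with Rubin's rules;
#' optionally also within risk-defined subgroups.
#'
#' @param cohort a [cd_cohort].
#' @param outcome outcome flag name (default `"ssfr_star"`).
#' @param horizon_month outcome horizon.
#' @param m,iterations imputation controls (see [chained_impute()]).
#' @param n_reps bootstrap replicates per imputation.
#' @param lambda ridge penalty.
#' @param subgroup `"none"`, `"activity"` or `"popo"`.
#' @param seed master seed for imputation and bootstrap.
#' @param thresholds,ref_table passed to [build_analysis_data()].
#' @return list: `estimates` (pooled tibble), `subgroups` (or `NULL`),
#'   `stack`, `data`, `spec`.
#' @export
estimate_effect <- function(cohort, outcome = "ssfr_star", horizon_month = 12,
                            m = 30L, iterations = 10L, n_reps = 1000L,
                            lambda = 0.125,
                            subgroup = c("none", "activity", "popo"),
                            seed = 1L,
                            thresholds = analysis_thresholds(),
                            ref_table = lms_reference_synthetic()) {
  subgroup <- match.arg(subgroup)
  dat <- build_analysis_data(cohort, outcome = outcome,
                             horizon_month = horizon_month,
                             thresholds = thresholds, ref_table = ref_table)
  seeds <- substream_seeds(seed, 2L)
  model_cols <- c("outcome", "early_antitnf", model_spec()$covariates)
  aux_cols <- c("wpcdai", "fcp", "esr", "sescd_total")
  imp_frame <- dat[, c("id", model_cols, aux_cols)]
  stack <- chained_impute(imp_frame, m = m, iterations = iterations,
                          seed = seeds[1])
  spec <- model_spec(outcome = "outcome", lambda = lambda)
  completed <- complete_all(stack)
  est <- estimate_pooled(completed, spec, n_reps = n_reps, seed = seeds[2])
  subs <- if (subgroup != "none") {
    subgroup_estimates(completed, spec, stratifier = subgroup,
                       n_reps = n_reps, seed = seeds[2])
  } else {
    NULL
  }
  list(estimates = est, subgroups = subs, stack = stack, data = dat,
       spec = spec)
}
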
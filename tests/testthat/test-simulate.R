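test_that("simulation is deterministic given (config, seed)", {
  cfg <- sim_config(n = 80, seed = 5)
  c1 <- simulate_cohort(cfg, seed = 9)
  c2 <- simulate_cohort(cfg, seed = 9)
  for (tab in c("baseline", "visits", "therapies", "events")) {
    expect_identical(c1[[tab]], c2[[tab]], info = tab)
  }
  expect_identical(cohort_truth(c1), cohort_truth(c2))
  s1 <- draw_analysis_sample(cfg, seed = 9)
  s2 <- draw_analysis_sample(cfg, seed = 9)
  expect_identical(s1, s2)
})

test_that("a null propensity with a logit(0.41) intercept treats ~41%", {
  cfg <- sim_config(
    n = 1e5, seed = 1,
    propensity = list(intercept = qlogis(0.41),
                      coefs = c(moderate_severe_activity = 0, perianal = 0,
                                deep_colonic_ulcers = 0, extensive_disease = 0,
                                growth_delay = 0, complicated_disease = 0,
                                crp = 0, age_years = 0)))
  s <- draw_analysis_sample(cfg, seed = 2)
  se <- sqrt(0.41 * 0.59 / 1e5)
  expect_lt(abs(mean(s$early_antitnf) - 0.41), 4 * se)
})

test_that("default study conditions: ~41% treated and Table-1-like marginals", {
  cfg <- sim_config(n = 1e4, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 3)
  bin_se <- function(p) sqrt(p * (1 - p) / 1e4)
  expect_lt(abs(mean(s$early_antitnf) - 0.41), 4 * bin_se(0.41))
  expect_lt(abs(mean(s$sex == "M") - 0.62), 4 * bin_se(0.62))
  ## moderate-to-severe activity about two-thirds of the cohort
  expect_gt(mean(s$moderate_severe_activity), 0.55)
  expect_lt(mean(s$moderate_severe_activity), 0.75)
  ## most patients carry at least one predictor of poor outcome
  expect_gt(mean(s$any_popo), 0.55)
  expect_lt(mean(s$any_popo), 0.85)
})

test_that("a zero treatment coefficient yields a null effect", {
  cfg <- sim_config(n = 2e4, seed = 1, outcome = list(treatment = 0))
  s <- draw_analysis_sample(cfg, seed = 4)
  tr <- attr(s, "truth")
  expect_identical(tr$y0, tr$y1)
  te <- true_marginal_effects(cfg, n_mc = 1e4, seed = 5)
  expect_equal(te$true_marginal_rr, 1, tolerance = 1e-12)
  ## with treatment also assigned at random the crude RR sits at 1
  cfg0 <- sim_config(
    n = 2e4, seed = 1, outcome = list(treatment = 0),
    propensity = list(coefs = c(moderate_severe_activity = 0, perianal = 0,
                                deep_colonic_ulcers = 0, extensive_disease = 0,
                                growth_delay = 0, complicated_disease = 0,
                                crp = 0, age_years = 0)))
  s0 <- draw_analysis_sample(cfg0, seed = 4)
  rr0 <- mean(s0$ssfr_star[s0$early_antitnf]) /
    mean(s0$ssfr_star[!s0$early_antitnf])
  expect_gt(rr0, 0.88); expect_lt(rr0, 1.13)
})

test_that("the oracle matches the closed form when covariate effects vanish", {
  cfg <- sim_config(n = 100, seed = 1, outcome = list(
    intercept = -1, treatment = 0.8,
    coefs = c(age_years = 0, sexM = 0, moderate_severe_activity = 0,
              crp = 0, perianal = 0, deep_colonic_ulcers = 0,
              extensive_disease = 0, growth_delay = 0,
              complicated_disease = 0)))
  te <- true_marginal_effects(cfg, n_mc = 1e4, seed = 6)
  expect_equal(te$p0_true, plogis(-1), tolerance = 1e-12)
  expect_equal(te$p1_true, plogis(-0.2), tolerance = 1e-12)
  expect_equal(te$true_marginal_rr, plogis(-0.2) / plogis(-1),
               tolerance = 1e-12)
  expect_equal(te$true_marginal_or, exp(0.8), tolerance = 1e-12)
})

test_that("the true RR increases monotonically with the treatment coefficient", {
  rrs <- vapply(c(0, 0.5, 1.0, 1.5), function(b) {
    cfg <- sim_config(n = 100, seed = 1, outcome = list(treatment = b))
    true_marginal_effects(cfg, n_mc = 2e4, seed = 7)$true_marginal_rr
  }, numeric(1))
  expect_true(all(diff(rrs) > 0))
})

test_that("confounding by indication biases the crude RR towards the null", {
  cfg <- sim_config(n = 4e4, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 8)
  crude <- mean(s$ssfr_star[s$early_antitnf]) /
    mean(s$ssfr_star[!s$early_antitnf])
  te <- true_marginal_effects(cfg, n_mc = 4e4, seed = 9)
  ## sicker patients are treated and do worse, so crude < true
  expect_lt(crude, te$true_marginal_rr - 3 * te$mc_se)

  ## with treatment assigned independently of covariates, crude ~ true
  cfg0 <- sim_config(
    n = 4e4, seed = 1,
    propensity = list(coefs = c(moderate_severe_activity = 0, perianal = 0,
                                deep_colonic_ulcers = 0, extensive_disease = 0,
                                growth_delay = 0, complicated_disease = 0,
                                crp = 0, age_years = 0)))
  s0 <- draw_analysis_sample(cfg0, seed = 8)
  crude0 <- mean(s0$ssfr_star[s0$early_antitnf]) /
    mean(s0$ssfr_star[!s0$early_antitnf])
  te0 <- true_marginal_effects(cfg0, n_mc = 4e4, seed = 9)
  expect_lt(abs(crude0 - te0$true_marginal_rr), 0.2)
})

test_that("missingness injection hits the configured rates and honours zero", {
  cfg <- config_no_missingness(n = 800, seed = 11)
  coh <- simulate_cohort(cfg, seed = 12)
  complete <- attr(coh, "complete")
  expect_identical(coh$baseline, complete$baseline)

  cfg2 <- cfg
  cfg2$missingness$visits[["fcp"]] <- 0.55
  out <- inject_missingness(complete, cfg2, seed = 13)
  frac_obs <- mean(!is.na(out$visits$fcp))
  n <- nrow(out$visits)
  expect_lt(abs(frac_obs - 0.45), 4 * sqrt(0.45 * 0.55 / n))
  ## observed values are unchanged
  obs <- !is.na(out$visits$fcp)
  expect_identical(out$visits$fcp[obs], complete$visits$fcp[obs])

  cfg_bad <- cfg
  cfg_bad$missingness$visits[["fcp"]] <- 1.5
  expect_error(inject_missingness(complete, cfg_bad, seed = 1), "missingness")
})

test_that("missing-at-random FCP deletion tracks disease activity", {
  cfg <- config_no_missingness(n = 3000, seed = 14)
  coh <- simulate_cohort(cfg, seed = 15)
  complete <- attr(coh, "complete")
  cfg$missingness$visits[["fcp"]] <- 0.5
  cfg$missingness$mar$fcp_on_wpcdai <- 1.0
  out <- inject_missingness(complete, cfg, seed = 16)
  v <- out$visits
  sev <- (complete$visits$wpcdai - 30) / 20
  fit <- stats::glm(is.na(v$fcp) ~ sev, family = binomial)
  expect_equal(unname(coef(fit)["sev"]), 1.0, tolerance = 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n = 0), "n must be")
  expect_error(sim_config(covariate_params = list(sex_male = 1.4)), "rate")
  expect_error(sim_config(failure_modes = list(early = c(
    act_mild = 0.5, act_modsev = 0.5, steroid = 0.2, intens = 0.1))),
    "sum to 1")
})
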
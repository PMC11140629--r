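test_that("the unpenalised fit reproduces the maximum-likelihood solution", {
  set.seed(101)
  n <- 400
  x <- cbind(treatment = rbinom(n, 1, 0.4), age = rnorm(n, 13, 2),
             sev = rbinom(n, 1, 0.6))
  eta <- -1 + 0.9 * x[, 1] - 0.1 * (x[, 2] - 13) - 0.5 * x[, 3]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_ridge_logistic(x, y, lambda = 0)
  ml <- stats::glm(y ~ x, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ml)), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("a huge penalty shrinks coefficients to zero and the intercept to the base rate", {
  set.seed(102)
  n <- 300
  x <- cbind(treatment = rbinom(n, 1, 0.5), z = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + x[, 1]))
  fit <- fit_ridge_logistic(x, y, lambda = 1e6)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-3)
  expect_equal(fit$beta0, qlogis(mean(y)), tolerance = 1e-3)
})

test_that("the ridge penalty rescues perfectly separated data", {
  x <- cbind(treatment = c(0, 0, 0, 0, 1, 1, 1, 1),
             z = c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- fit_ridge_logistic(x, y, lambda = 1)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_error(fit_ridge_logistic(x, y, lambda = 0), "converge")
  expect_error(fit_ridge_logistic(x, y * 0, lambda = 1), "single class")
})

test_that("standardisation with a null treatment coefficient is exactly null", {
  fit <- as_ridge_fit(c("(Intercept)" = -0.7, treatment = 0, sev = 0.8))
  x <- cbind(treatment = c(1, 0, 1, 0), sev = c(0, 0, 1, 1))
  eff <- standardize(fit, x)
  expect_identical(eff$rr, 1)
  expect_identical(eff$or, 1)
  expect_identical(eff$rd, 0)
})

test_that("with no covariates the standardised RR equals the crude risk ratio", {
  set.seed(103)
  n <- 500
  trt <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * trt))
  x <- cbind(treatment = trt)
  fit <- fit_ridge_logistic(x, y, lambda = 0)
  eff <- standardize(fit, x)
  crude <- mean(y[trt == 1]) / mean(y[trt == 0])
  expect_equal(eff$rr, crude, tolerance = 1e-8)
  expect_equal(eff$p_bar_1, mean(y[trt == 1]), tolerance = 1e-8)
})

test_that("OR and RR always sit on the same side of 1 with |log OR| >= |log RR|", {
  set.seed(104)
  cfg <- sim_config(n = 600, seed = 1)
  for (b in c(-0.8, 0.4, 1.2)) {
    cfgb <- sim_config(n = 600, seed = 1, outcome = list(treatment = b))
    s <- draw_analysis_sample(cfgb, seed = round(10 * abs(b)) + 1)
    des <- earlytnf:::build_design(s, model_spec(outcome = "ssfr_star"))
    fit <- fit_ridge_logistic(des$x, des$y, lambda = 0.125)
    eff <- standardize(fit, des$x)
    expect_equal(sign(log(eff$or)), sign(log(eff$rr)))
    expect_gte(abs(log(eff$or)), abs(log(eff$rr)))
  }
})

test_that("the compiled bootstrap refit agrees with the R reference fit", {
  cfg <- sim_config(n = 300, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 19)
  des <- earlytnf:::build_design(s, model_spec(outcome = "ssfr_star"))
  x <- des$x; y <- des$y
  full <- fit_ridge_logistic(x, y, lambda = 0.125)
  xs <- sweep(sweep(x, 2, full$center), 2, full$scale, "/")
  X <- cbind(1, xs)
  tcol <- which(colnames(x) == "treatment") + 1L
  d <- c(0, rep(0.125, ncol(x)))
  v1 <- (1 - full$center[tcol - 1]) / full$scale[tcol - 1]
  v0 <- (0 - full$center[tcol - 1]) / full$scale[tcol - 1]
  idx <- withr::with_seed(7, matrix(sample.int(300, 300 * 25, TRUE), 300, 25))
  cpp <- earlytnf:::boot_replicates_cpp(X, y, d, full$beta_internal,
                                        idx - 1L, tcol - 1L, v1, v0,
                                        30L, 1e-8)
  rref <- t(apply(idx, 2, function(ii) {
    fb <- earlytnf:::ridge_irls(X[ii, ], y[ii], d,
                                beta = full$beta_internal,
                                max_iter = 30, tol = 1e-8)
    base <- drop(X[ii, ] %*% fb$beta)
    p1 <- mean(plogis(base + (v1 - X[ii, tcol]) * fb$beta[tcol]))
    p0 <- mean(plogis(base + (v0 - X[ii, tcol]) * fb$beta[tcol]))
    c(log(p1 / p0), log(p1 / (1 - p1)) - log(p0 / (1 - p0)), p1 - p0)
  }))
  expect_lt(max(abs(cpp - rref)), 1e-10)
})

test_that("the bootstrap is reproducible and its variance behaves", {
  cfg <- sim_config(n = 400, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 11)
  spec <- model_spec(outcome = "ssfr_star")
  b1 <- bootstrap_effect(s, spec, n_reps = 50, seed = 42)
  b2 <- bootstrap_effect(s, spec, n_reps = 50, seed = 42)
  expect_identical(b1$point, b2$point)
  expect_identical(b1$variance, b2$variance)
  expect_equal(b1$failures, 0L)
  expect_true(all(b1$variance > 0))
  expect_error(bootstrap_effect(s, spec, n_reps = 1, seed = 1), "n_reps")
})

test_that("pooling identical datasets leaves no between-imputation variance", {
  cfg <- sim_config(n = 300, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 12)
  spec <- model_spec(outcome = "ssfr_star")
  est <- estimate_pooled(list(s, s, s), spec, n_reps = 60, seed = 5)
  per <- attr(est, "per_imputation")
  expect_equal(max(apply(per$points, 2, var)), 0)
  rr <- est[est$scale == "rr", ]
  expect_equal(rr$t_total, mean(per$variances[, "log_rr"]))
  expect_equal(rr$df, Inf)
})

test_that("subgroup estimation drops within-stratum constants and recovers ordering", {
  ## generator with a treatment-by-activity interaction: the effect is
  ## larger in the moderate/severe stratum
  cfg <- sim_config(n = 4000, seed = 1,
                    outcome = list(treatment = 0.5, interaction_modsev = 0.9))
  s <- draw_analysis_sample(cfg, seed = 13)
  spec <- model_spec(outcome = "ssfr_star")
  subs <- suppressWarnings(subgroup_estimates(list(s), spec,
                                              stratifier = "activity",
                                              n_reps = 40, seed = 6))
  rr_low <- subs$mild_inactive[subs$mild_inactive$scale == "rr", ]$estimate
  rr_high <- subs$moderate_severe[subs$moderate_severe$scale == "rr", ]$estimate
  expect_gt(rr_high, rr_low)

  ## homogeneous cohort: one stratum empty, the other equals the whole cohort
  shigh <- s[s$moderate_severe_activity, ]
  subs2 <- suppressWarnings(subgroup_estimates(list(shigh), spec,
                                               stratifier = "activity",
                                               n_reps = 40, seed = 7))
  expect_null(subs2$mild_inactive)
  spec_high <- spec
  spec_high$covariates <- setdiff(spec$covariates, "moderate_severe_activity")
  whole <- estimate_pooled(list(shigh), spec_high, n_reps = 40, seed = 7)
  expect_equal(subs2$moderate_severe$estimate, whole$estimate)

  ## POPO stratification: the no-POPO stratum drops the constant flags
  subs3 <- suppressWarnings(subgroup_estimates(list(s), spec,
                                               stratifier = "popo",
                                               n_reps = 40, seed = 8))
  expect_false(is.null(subs3$no_popo))
  expect_false(is.null(subs3$any_popo))
})
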
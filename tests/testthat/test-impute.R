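test_that("Rubin pooling reproduces hand arithmetic and degenerate cases", {
  pr <- pool_rubin(c(1.0, 1.2, 1.4), c(0.04, 0.04, 0.04))
  expect_equal(pr$q_bar, 1.2)
  expect_equal(pr$u_bar, 0.04)
  expect_equal(pr$b_between, 0.04)
  expect_equal(pr$t_total, 0.04 + (4 / 3) * 0.04)
  expect_true(pr$ci_low <= pr$q_bar && pr$q_bar <= pr$ci_high)

  ## identical estimates: no between-imputation variance
  pr0 <- pool_rubin(c(2, 2, 2), c(0.1, 0.1, 0.1))
  expect_equal(pr0$b_between, 0)
  expect_equal(pr0$t_total, 0.1)
  expect_equal(pr0$df, Inf)

  ## scale equivariance: c * estimates, c^2 * variances
  pr2 <- pool_rubin(3 * c(1.0, 1.2, 1.4), 9 * c(0.04, 0.04, 0.04))
  expect_equal(pr2$q_bar, 3 * pr$q_bar)
  expect_equal(pr2$t_total, 9 * pr$t_total)
  expect_equal(pr2$df, pr$df)

  expect_error(pool_rubin(1, 0.1), "two imputations")
  expect_error(pool_rubin(c(1, 2), c(-0.1, 0.1)), "non-negative")
})

test_that("a complete dataset passes through imputation unchanged", {
  cfg <- sim_config(n = 60, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 21)
  st <- chained_impute(s[, c("id", "age_years", "crp", "sex")], m = 3,
                       iterations = 2, seed = 2)
  for (i in 1:3) {
    expect_identical(complete_data(st, i),
                     s[, c("id", "age_years", "crp", "sex")])
  }
})

test_that("predictive-mean matching imputes observed donor values only", {
  cfg <- sim_config(n = 200, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 22)
  d <- s[, c("id", "crp", "age_years", "wpcdai", "moderate_severe_activity")]
  d <- mcar_delete(d, "crp", 0.25, seed = 3)
  st <- chained_impute(d, m = 4, iterations = 4, seed = 4)
  donors <- d$crp[!is.na(d$crp)]
  for (i in 1:4) {
    ci <- complete_data(st, i)
    expect_true(all(ci$crp[is.na(d$crp)] %in% donors))
    ## observed cells identical across the stack
    expect_identical(ci$crp[!is.na(d$crp)], donors)
  }
})

test_that("binary and categorical targets use their conditional models", {
  cfg <- sim_config(n = 300, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 23)
  d <- s[, c("id", "crp", "moderate_severe_activity", "growth_delay", "sex")]
  d$risk_band <- cut(s$wpcdai, c(-Inf, 25, 50, Inf),
                     labels = c("low", "mid", "high"))
  d <- mcar_delete(d, "moderate_severe_activity", 0.2, seed = 5)
  d <- mcar_delete(d, "risk_band", 0.2, seed = 6)
  st <- chained_impute(d, m = 3, iterations = 3, seed = 7)
  expect_equal(unname(st$methods[c("moderate_severe_activity", "risk_band")]),
               c("logreg", "polyreg"))
  c1 <- complete_data(st, 1)
  expect_type(c1$moderate_severe_activity, "logical")
  expect_true(all(!is.na(c1$moderate_severe_activity)))
  expect_true(all(c1$risk_band %in% levels(d$risk_band)))
})

test_that("a variable with no observed values is an error", {
  d <- tibble::tibble(id = letters[1:5], x = NA_real_, y = 1:5)
  expect_error(chained_impute(d, m = 2, iterations = 1, seed = 1),
               "no observed values")
})

test_that("constant variables are dropped from the predictors with a warning", {
  d <- tibble::tibble(id = letters[1:10], x = c(rnorm(8), NA, NA),
                      y = rnorm(10), konst = 1)
  ## at this tiny size the chain-drift warning may legitimately fire too
  w <- capture_warnings(st <- chained_impute(d, m = 2, iterations = 2,
                                             seed = 1))
  expect_match(w, "konst", all = FALSE)
  expect_false(anyNA(complete_data(st, 1)$x))
})

test_that("imputation under MCAR recovers the complete-data mean", {
  cfg <- sim_config(n = 2000, seed = 1)
  s <- draw_analysis_sample(cfg, seed = 24)
  d <- s[, c("id", "crp", "age_years", "wpcdai",
             "moderate_severe_activity", "fcp")]
  full_mean <- mean(d$crp)
  d <- mcar_delete(d, "crp", 0.2, seed = 8)
  st <- chained_impute(d, m = 5, iterations = 5, seed = 9)
  means <- vapply(complete_all(st), function(ci) mean(ci$crp), numeric(1))
  vars <- vapply(complete_all(st),
                 function(ci) var(ci$crp) / nrow(ci), numeric(1))
  pr <- pool_rubin(means, vars)
  expect_lt(abs(pr$q_bar - full_mean), 3 * sqrt(pr$t_total))
})

test_that("pooled intervals for a mean under MCAR cover at the nominal rate", {
  ## 200 small replicates with m = 5: coverage should sit near 95%.
  ## Target: the closed-form mean of the truncated-normal age distribution.
  covered <- logical(200)
  cfg <- sim_config(n = 150, seed = 1)
  cp <- cfg$covariate_params
  a <- (cp$age_min - cp$age_mean) / cp$age_sd
  b <- (cp$age_max - cp$age_mean) / cp$age_sd
  mu_pop <- cp$age_mean + cp$age_sd * (dnorm(a) - dnorm(b)) /
    (pnorm(b) - pnorm(a))
  for (r in seq_len(200)) {
    s <- draw_analysis_sample(cfg, seed = 3000 + r)
    d <- s[, c("id", "age_years", "crp", "wpcdai")]
    d <- mcar_delete(d, "age_years", 0.3, seed = 5000 + r)
    st <- chained_impute(d, m = 5, iterations = 3, seed = 7000 + r)
    means <- vapply(complete_all(st), function(ci) mean(ci$age_years),
                    numeric(1))
    vars <- vapply(complete_all(st),
                   function(ci) var(ci$age_years) / nrow(ci), numeric(1))
    pr <- pool_rubin(means, vars)
    covered[r] <- pr$ci_low <= mu_pop && mu_pop <= pr$ci_high
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.98)
})
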
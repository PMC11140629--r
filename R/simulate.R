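## ----------------------------------------------------------------------------
## Synthetic cohort generator. One latent severity process drives disease
## activity, biomarkers, predictors of poor outcome, treatment assignment
## (confounding by indication) and outcomes, so that the estimator's
## confounders genuinely confound. Potential outcomes are generated under
## consistency and no interference; the Monte-Carlo oracle is the definition
## of the marginal estimand the standardisation targets.
## ----------------------------------------------------------------------------

FAILURE_MODES <- c("act_mild", "act_modsev", "steroid", "intens")

#' Simulation configuration
#'
#' Assembles the full data-generating mechanism: baseline covariate
#' distributions (tuned so the generated marginals resemble a real paediatric
#' Crohn's inception cohort: ~62% male, median age ~13.7 years, ~67%
#' moderate-to-severe activity, ~41% treated early), a logistic
#' treatment-assignment (propensity) model whose coefficients encode
#' confounding by indication, a logistic model for the 1-year primary
#' outcome (sustained steroid-free remission without intensification) whose
#' treatment coefficient is the true conditional log odds ratio, arm-specific
#' failure-mode probabilities that shape the milder sustained outcome, visit
#' trajectory parameters, and per-variable missingness rates (faecal
#' calprotectin above 50% by default).
#'
#' Intercepts left `NA` are calibrated by simulation (fixed internal stream)
#' so that the marginal treated fraction and the marginal untreated outcome
#' risk hit their targets.
#'
#' @param n cohort size.
#' @param seed default seed used by [simulate_cohort()] when none is given.
#' @param covariate_params,propensity,outcome,failure_modes,trajectory,missingness
#'   named lists overriding individual defaults (merged with
#'   [utils::modifyList()]; vectors are replaced wholesale).
#' @param visit_months protocol visit schedule.
#' @param dropout_rate fraction flagged as dropped out before 1 year.
#' @param calibration_n sample size of the internal calibration draw.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n = 331, seed = 1L,
                       covariate_params = list(), propensity = list(),
                       outcome = list(), failure_modes = list(),
                       trajectory = list(), missingness = list(),
                       visit_months = c(0, 3, 6, 12, 18, 24),
                       dropout_rate = 0, calibration_n = 20000L) {
  cp <- utils::modifyList(list(
    age_mean = 13.2, age_sd = 2.7, age_min = 2.1, age_max = 18,
    sex_male = 0.62,
    ttd_meanlog = log(150), ttd_sdlog = 0.9,
    crp_meanlog = log(1.8), crp_sdlog = 0.8, crp_sev = 0.55,
    esr_meanlog = log(30), esr_sdlog = 0.55, esr_sev = 0.3,
    fcp_meanlog = log(900), fcp_sdlog = 0.75, fcp_sev = 0.5,
    wpcdai_mean = 47, wpcdai_sd = 15, wpcdai_sev = 14,
    location_probs = c(L1 = 0.25, L2 = 0.17, L3 = 0.56, L4 = 0.02),
    upper_gi_probs = c(none = 0.48, L4a = 0.44, L4b = 0.07, L4ab = 0.01),
    behaviour_probs = c(B1 = 0.87, B2 = 0.08, B3 = 0.04, B2B3 = 0.01),
    b1_narrowing = 0.05,
    perianal_logit = c(intercept = qlogis(0.17), severity = 0.35),
    deep_ulcer_logit = c(intercept = -0.6, severity = 0.9),
    sescd_base = 12, sescd_sev = 4.5, sescd_noise = 5,
    hfa_mean = -0.09, hfa_sd = 1.19,
    bmi_mean = -0.96, bmi_sd = 1.51
  ), covariate_params)

  pr <- utils::modifyList(list(
    intercept = NA_real_, target_treated_fraction = 0.41,
    coefs = c(moderate_severe_activity = 0.45, perianal = 0.75,
              deep_colonic_ulcers = 0.3, extensive_disease = 0.3,
              growth_delay = 0.2, complicated_disease = 0.25,
              crp = 0.04, age_years = 0.03)
  ), propensity)

  oc <- utils::modifyList(list(
    intercept = NA_real_, target_p0 = 0.14,
    treatment = log(3.1), interaction_modsev = 0,
    coefs = c(age_years = -0.03, sexM = 0.10,
              moderate_severe_activity = -0.55, crp = -0.10,
              perianal = -0.25, deep_colonic_ulcers = -0.30,
              extensive_disease = -0.30, growth_delay = -0.30,
              complicated_disease = -0.35)
  ), outcome)

  fm <- utils::modifyList(list(
    early = c(act_mild = 0.56, act_modsev = 0.28, steroid = 0.10,
              intens = 0.06),
    noearly = c(act_mild = 0.22, act_modsev = 0.50, steroid = 0.18,
                intens = 0.10)
  ), failure_modes)

  tj <- utils::modifyList(list(
    persist_remission = 0.8, act_mild_prob = 0.6,
    upfront_given_early = 0.47,
    induction_early = c(een = 0.35, corticosteroid = 0.14, none = 0.04),
    induction_noearly = c(een = 0.69, corticosteroid = 0.21, `5asa` = 0.05,
                          none = 0.05),
    imm_prob = 0.72, inclass_switch_prob = 0.05,
    dose_intensified_prob = 0.15,
    surgery_given_intens = c(early = 0.3, noearly = 0.2),
    delta_hfa_1y = c(early = 0.05, noearly = 0.01),
    delta_hfa_1y_sd = c(early = 0.39, noearly = 0.59),
    delta_bmi_1y = c(early = 1.18, noearly = 0.88),
    delta_bmi_1y_sd = c(early = 1.05, noearly = 1.07),
    delta_hfa_2y = c(early = 0.15, noearly = 0.20),
    delta_hfa_2y_sd = c(early = 0.62, noearly = 0.60),
    delta_bmi_2y = c(early = 1.41, noearly = 1.05),
    delta_bmi_2y_sd = c(early = 1.30, noearly = 1.07),
    delta_impact3 = c(early = 12.5, noearly = 10.5), delta_impact3_sd = 15,
    delta_vas = c(early = 17.4, noearly = 9.8), delta_vas_sd = 20
  ), trajectory)

  ms <- utils::modifyList(list(
    baseline = c(wpcdai = 0.23, pga = 0.015, crp = 0.05, esr = 0.05,
                 fcp = 0.55, perianal = 0.03, behaviour = 0.005,
                 paris_location = 0.02, upper_gi = 0.02,
                 height_cm = 0.04, weight_kg = 0.04,
                 time_to_diagnosis_days = 0.04),
    endoscopy_block = 0.29,
    visits = c(status = 0.04, wpcdai = 0.10, crp = 0.12, fcp = 0.55,
               mini_index = 0.25, height_cm = 0.20, weight_kg = 0.20,
               impact3_total = 0.30, eq5d_vas = 0.30),
    mar = list(fcp_on_wpcdai = 0)
  ), missingness)

  for (v in list(cp$location_probs, cp$upper_gi_probs, cp$behaviour_probs,
                 fm$early, fm$noearly)) {
    check_prob(v, "probability parameter")
    if (abs(sum(v) - 1) > 1e-8) {
      stop("probability vectors must sum to 1", call. = FALSE)
    }
  }
  check_prob(c(ms$baseline, ms$visits, ms$endoscopy_block,
               cp$sex_male, cp$b1_narrowing, dropout_rate,
               pr$target_treated_fraction, oc$target_p0),
             "rate parameter")
  if (!setequal(names(fm$early), FAILURE_MODES) ||
      !setequal(names(fm$noearly), FAILURE_MODES)) {
    stop("failure-mode probabilities must be named ",
         paste(FAILURE_MODES, collapse = ", "), call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)

  cfg <- structure(list(n = n, seed = seed, covariate_params = cp,
                        propensity = pr, outcome = oc, failure_modes = fm,
                        trajectory = tj, missingness = ms,
                        visit_months = visit_months,
                        dropout_rate = dropout_rate),
                   class = "sim_config")
  calibrate_intercepts(cfg, calibration_n)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> n = %d, true conditional log-OR = %.3f, ",
                     "target treated fraction = %.2f, target p0 = %.2f\n"),
              x$n, x$outcome$treatment, x$propensity$target_treated_fraction,
              x$outcome$target_p0))
  invisible(x)
}

## linear predictors (excluding intercepts) for the covariate draw
propensity_lp0 <- function(cov, pr) {
  co <- pr$coefs
  drop(as.matrix(cov[, names(co)]) %*% co)
}
outcome_lp0 <- function(cov, oc) {
  co <- oc$coefs
  x <- cov
  x$sexM <- as.numeric(cov$sex == "M")
  drop(as.matrix(x[, names(co)]) %*% co)
}

## fixed-stream calibration of NA intercepts to the marginal targets
calibrate_intercepts <- function(cfg, n_cal) {
  if (!is.na(cfg$propensity$intercept) && !is.na(cfg$outcome$intercept)) {
    return(cfg)
  }
  cov <- with_seed(20170101L, draw_covariates(cfg, n_cal))
  solve_intercept <- function(lp, target) {
    stats::uniroot(function(c0) mean(plogis(c0 + lp)) - target,
                   lower = -25, upper = 25, tol = 1e-10)$root
  }
  if (is.na(cfg$propensity$intercept)) {
    cfg$propensity$intercept <-
      solve_intercept(propensity_lp0(cov, cfg$propensity),
                      cfg$propensity$target_treated_fraction)
  }
  if (is.na(cfg$outcome$intercept)) {
    cfg$outcome$intercept <-
      solve_intercept(outcome_lp0(cov, cfg$outcome), cfg$outcome$target_p0)
  }
  cfg
}

## draw baseline covariates and latents; assumes an active RNG stream
draw_covariates <- function(cfg, n) {
  cp <- cfg$covariate_params
  z_sev <- rnorm(n)
  age <- rtruncnorm(n, cp$age_mean, cp$age_sd, cp$age_min, cp$age_max)
  sex <- ifelse(runif(n) < cp$sex_male, "M", "F")
  crp <- rlnorm(n, cp$crp_meanlog + cp$crp_sev * z_sev, cp$crp_sdlog)
  esr <- rlnorm(n, cp$esr_meanlog + cp$esr_sev * z_sev, cp$esr_sdlog)
  fcp <- rlnorm(n, cp$fcp_meanlog + cp$fcp_sev * z_sev, cp$fcp_sdlog)
  wpcdai <- pmin(127.5, pmax(0, cp$wpcdai_mean + cp$wpcdai_sev * z_sev +
                               rnorm(n, 0, cp$wpcdai_sd)))
  location <- sample(names(cp$location_probs), n, TRUE, cp$location_probs)
  upper_gi <- sample(names(cp$upper_gi_probs), n, TRUE, cp$upper_gi_probs)
  behaviour <- sample(names(cp$behaviour_probs), n, TRUE, cp$behaviour_probs)
  b1_narrow <- behaviour == "B1" & runif(n) < cp$b1_narrowing
  perianal <- runif(n) < plogis(cp$perianal_logit["intercept"] +
                                  cp$perianal_logit["severity"] * z_sev)
  deep <- runif(n) < plogis(cp$deep_ulcer_logit["intercept"] +
                              cp$deep_ulcer_logit["severity"] * z_sev)
  hfa_z <- rnorm(n, cp$hfa_mean, cp$hfa_sd)
  bmi_z <- rnorm(n, cp$bmi_mean, cp$bmi_sd)
  sescd <- pmin(56, round(pmax(0, cp$sescd_base + cp$sescd_sev * z_sev +
                                 rnorm(n, 0, cp$sescd_noise))))
  tibble(
    z_sev = z_sev, age_years = age, sex = sex,
    time_to_diagnosis_days = round(rlnorm(n, cp$ttd_meanlog, cp$ttd_sdlog)),
    crp = round(crp, 2), esr = round(esr, 1), fcp = round(fcp, 1),
    wpcdai = round(wpcdai * 2) / 2,
    paris_location = location, upper_gi = upper_gi, behaviour = behaviour,
    b1_narrowing_no_dilatation = b1_narrow,
    perianal = perianal, deep_colonic_ulcers = deep,
    extensive_disease = location == "L3" & upper_gi != "none",
    growth_delay = hfa_z < -1.5,
    complicated_disease = behaviour %in% c("B2", "B3", "B2B3") |
      (behaviour == "B1" & b1_narrow),
    moderate_severe_activity = wpcdai > analysis_thresholds()$wpcdai_cuts[2],
    hfa_z = hfa_z, bmi_z = bmi_z, sescd_total = sescd
  )
}

## assign treatment, draw both potential outcomes and failure modes
draw_mechanism <- function(cfg, cov) {
  n <- nrow(cov)
  a <- runif(n) < plogis(cfg$propensity$intercept +
                           propensity_lp0(cov, cfg$propensity))
  lp0 <- cfg$outcome$intercept + outcome_lp0(cov, cfg$outcome)
  trt_eff <- cfg$outcome$treatment +
    cfg$outcome$interaction_modsev * cov$moderate_severe_activity
  p0 <- plogis(lp0)
  p1 <- plogis(lp0 + trt_eff)
  u <- runif(n)
  y0 <- u < p0
  y1 <- u < p1
  y <- ifelse(a, y1, y0)

  v <- runif(n)
  pick_mode <- function(probs) {
    FAILURE_MODES[findInterval(v, cumsum(probs), left.open = TRUE) + 1L]
  }
  mode1 <- pick_mode(cfg$failure_modes$early)
  mode0 <- pick_mode(cfg$failure_modes$noearly)
  mode <- ifelse(a, mode1, mode0)
  ssfmi0 <- y0 | mode0 == "act_mild"
  ssfmi1 <- y1 | mode1 == "act_mild"
  list(a = a, p0 = p0, p1 = p1, y0 = y0, y1 = y1, y = as.logical(y),
       mode = mode, mode0 = mode0, mode1 = mode1,
       ssfmi0 = ssfmi0, ssfmi1 = ssfmi1)
}

#' Draw an analysis-ready sample from the generative model
#'
#' The fast path for simulation experiments: draws baseline covariates,
#' confounded treatment assignment and the outcome flags directly from the
#' configured mechanism, skipping the construction of visit/therapy records.
#' By construction ([simulate_cohort()] writes records that the outcome
#' engine decodes back to exactly these labels when no missingness is
#' injected), estimator studies on this sample are equivalent to running the
#' full record-level pipeline.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`).
#' @param n sample size (default `config$n`).
#' @return a tibble with `id`, `early_antitnf`, the analysis covariates,
#'   `any_popo`, the outcome flags `ssfr_star` and `ssfmi_star`, and
#'   auxiliaries (`wpcdai`, `fcp`, `sescd_total`); the per-patient potential
#'   outcomes are attached as `attr(, "truth")`.
#' @export
draw_analysis_sample <- function(config, seed = config$seed, n = config$n) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    cov <- draw_covariates(config, n)
    mech <- draw_mechanism(config, cov)
    popo_cols <- c("perianal", "deep_colonic_ulcers", "extensive_disease",
                   "growth_delay", "complicated_disease")
    out <- tibble(
      id = sprintf("P%05d", seq_len(n)),
      early_antitnf = mech$a,
      age_years = cov$age_years, sex = cov$sex,
      moderate_severe_activity = cov$moderate_severe_activity,
      crp = cov$crp,
      perianal = cov$perianal,
      deep_colonic_ulcers = cov$deep_colonic_ulcers,
      extensive_disease = cov$extensive_disease,
      growth_delay = cov$growth_delay,
      complicated_disease = cov$complicated_disease,
      any_popo = apply(cov[, popo_cols], 1L, any),
      ssfr_star = mech$y,
      ssfmi_star = mech$y | mech$mode == "act_mild",
      wpcdai = cov$wpcdai, fcp = cov$fcp, sescd_total = cov$sescd_total
    )
    attr(out, "truth") <- tibble(
      id = out$id, a = mech$a, p0 = mech$p0, p1 = mech$p1,
      y0 = mech$y0, y1 = mech$y1,
      ssfmi_star0 = mech$ssfmi0, ssfmi_star1 = mech$ssfmi1)
    out
  })
}

#' Monte-Carlo oracle for the true marginal effects
#'
#' Computes the true marginal risks, risk ratio and odds ratio implied by
#' the configured mechanism by brute force over the potential-outcome
#' distribution: covariates are drawn from the configured distribution, both
#' potential risks are evaluated in closed form for every draw, and averaged.
#' This is the estimand regression standardisation targets; parameter
#' recovery tests compare pooled estimates against it.
#'
#' @param config a [sim_config()].
#' @param n_mc Monte-Carlo draws (>= 10000).
#' @param seed integer seed.
#' @param outcome `"ssfr_star"` (the logistic primary outcome) or
#'   `"ssfmi_star"` (which folds in the arm-specific mild-failure mass).
#' @return list of class `true_effects`: `p1_true`, `p0_true`,
#'   `true_marginal_rr`, `true_marginal_or`, `mc_se` (delta-method SE of the
#'   RR), `mc_se_p1`, `mc_se_p0`, `n_mc`.
#' @export
true_marginal_effects <- function(config, n_mc = 1e5, seed = 1L,
                                  outcome = c("ssfr_star", "ssfmi_star")) {
  stopifnot(inherits(config, "sim_config"))
  outcome <- match.arg(outcome)
  if (n_mc < 1e4) stop("n_mc must be at least 10000", call. = FALSE)
  with_seed(seed, {
    cov <- draw_covariates(config, n_mc)
    lp0 <- config$outcome$intercept + outcome_lp0(cov, config$outcome)
    trt_eff <- config$outcome$treatment +
      config$outcome$interaction_modsev * cov$moderate_severe_activity
    p0i <- plogis(lp0)
    p1i <- plogis(lp0 + trt_eff)
    if (outcome == "ssfmi_star") {
      p0i <- p0i + (1 - p0i) * config$failure_modes$noearly["act_mild"]
      p1i <- p1i + (1 - p1i) * config$failure_modes$early["act_mild"]
    }
    p1 <- mean(p1i); p0 <- mean(p0i)
    v1 <- var(p1i) / n_mc; v0 <- var(p0i) / n_mc
    cv <- stats::cov(p1i, p0i) / n_mc
    rr <- p1 / p0
    mc_se_rr <- rr * sqrt(v1 / p1^2 + v0 / p0^2 - 2 * cv / (p1 * p0))
    structure(list(
      p1_true = p1, p0_true = p0,
      true_marginal_rr = rr,
      true_marginal_or = (p1 / (1 - p1)) / (p0 / (1 - p0)),
      mc_se = mc_se_rr, mc_se_p1 = sqrt(v1), mc_se_p0 = sqrt(v0),
      n_mc = n_mc
    ), class = "true_effects")
  })
}

#' @export
print.true_effects <- function(x, ...) {
  cat(sprintf(paste0("<true_effects> p1 = %.4f, p0 = %.4f, RR = %.3f ",
                     "(MC SE %.4f), OR = %.3f\n"),
              x$p1_true, x$p0_true, x$true_marginal_rr, x$mc_se,
              x$true_marginal_or))
  invisible(x)
}

## sample a wPCDAI value consistent with an activity category; the bands
## leave a 0.3-point margin so rounding to half points cannot cross a cut
wpcdai_for_category <- function(cat) {
  n <- length(cat)
  lo <- c(remission = 0, mild = 12.8, moderate = 40.3, severe = 57.8)[cat]
  hi <- c(remission = 12.2, mild = 39.7, moderate = 57.2, severe = 95)[cat]
  round(runif(n, lo, hi) * 2) / 2
}

#' Simulate a full longitudinal cohort
#'
#' Generates complete patient records — baseline covariates, visit
#' trajectories at the protocol months, therapy courses (anti-TNF with
#' confounded assignment, induction EEN/steroids, immunomodulators,
#' escalations) and surgery events — such that running the outcome engine on
#' the records reproduces the generator's outcome labels exactly, then
#' injects the configured missingness. The complete (pre-missingness) cohort
#' and the truth table (potential outcomes, failure modes, and bookkeeping
#' outcome labels at both horizons) are attached as attributes.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`).
#' @return a [cd_cohort] with attributes `truth` (tibble) and `complete`
#'   (the pre-missingness [cd_cohort]).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- substream_seeds(seed, 3L)
  n <- config$n
  tj <- config$trajectory

  built <- with_seed(seeds[1], {
    cov <- draw_covariates(config, n)
    mech <- draw_mechanism(config, cov)
    id <- sprintf("P%05d", seq_len(n))
    a <- mech$a; y <- mech$y; mode <- mech$mode
    months <- sort(config$visit_months)
    fmonths <- months[months > 0]
    ref <- lms_reference_synthetic()

    ## --- per-visit activity categories consistent with the outcome labels
    core <- fmonths[fmonths <= 12]           # the sustained window months
    later <- fmonths[fmonths > 12]
    catm <- matrix("remission", n, length(fmonths),
                   dimnames = list(NULL, paste0("m", fmonths)))
    for (i in seq_len(n)) {
      ci <- rep("remission", length(core))
      if (!y[i] && mode[i] == "act_mild") {
        mild <- runif(length(core)) < tj$act_mild_prob
        if (!any(mild)) mild[sample.int(length(core), 1L)] <- TRUE
        ci[mild] <- "mild"
      } else if (!y[i] && mode[i] == "act_modsev") {
        sev <- sample.int(length(core), 1L)
        ci <- ifelse(runif(length(core)) < 0.5, "mild", "remission")
        ci[sev] <- sample(c("moderate", "severe"), 1L)
      }
      catm[i, seq_along(core)] <- ci
      prev <- ci[length(ci)]
      for (j in seq_along(later)) {
        prev <- switch(prev,
          remission = if (runif(1) < tj$persist_remission) "remission" else "mild",
          mild = sample(c("mild", "remission", "moderate"), 1L,
                        prob = c(0.6, 0.2, 0.2)),
          sample(c("moderate", "mild", "severe"), 1L, prob = c(0.5, 0.3, 0.2)))
        catm[i, length(core) + j] <- prev
      }
    }

    ## --- visit days: nominal month with +-7 day jitter, day 0 at baseline
    daym <- matrix(0, n, length(fmonths),
                   dimnames = list(NULL, paste0("m", fmonths)))
    for (j in seq_along(fmonths)) {
      daym[, j] <- round(30.4375 * fmonths[j] + runif(n, -7, 7))
    }
    day12 <- daym[, "m12"]

    ## --- therapies ------------------------------------------------------
    ther <- list()
    add <- function(tid, agent, start, stop, dose = FALSE) {
      ther[[length(ther) + 1L]] <<- tibble(
        id = tid, agent = agent, start_day = start, stop_day = stop,
        dose_intensified = dose)
    }
    trt <- which(a)
    if (length(trt)) {
      upfront <- runif(length(trt)) < tj$upfront_given_early
      start <- ifelse(upfront,
                      round(90 * stats::rbeta(length(trt), 1.05, 2.4)),
                      pmin(90, 6 + round(84 * stats::rbeta(length(trt), 1.05, 2.4))))
      agent <- sample(ANTITNF_AGENTS, length(trt), TRUE, c(0.67, 0.33))
      add(id[trt], agent, start,
          rep(NA_real_, length(trt)),
          runif(length(trt)) < tj$dose_intensified_prob)
      ## induction before the anti-TNF for the non-upfront treated
      ind <- trt[!upfront]
      if (length(ind)) {
        probs <- tj$induction_early / sum(tj$induction_early)
        choice <- sample(names(probs), length(ind), TRUE, probs)
        sel <- choice != "none"
        if (any(sel)) {
          st <- round(runif(sum(sel), 0, 4))
          dur <- ifelse(choice[sel] == "een", round(runif(sum(sel), 42, 56)),
                        round(runif(sum(sel), 45, 80)))
          add(id[ind[sel]], choice[sel], st, pmin(st + dur, 88))
        }
      }
      ## occasional in-class switch (never treatment escalation)
      sw <- trt[runif(length(trt)) < tj$inclass_switch_prob]
      if (length(sw)) {
        first <- agent[match(sw, trt)]
        other <- ifelse(first == "infliximab", "adalimumab", "infliximab")
        add(id[sw], other, round(runif(length(sw), 150, 300)), NA_real_)
      }
    }
    untrt <- which(!a)
    if (length(untrt)) {
      probs <- tj$induction_noearly / sum(tj$induction_noearly)
      choice <- sample(names(probs), length(untrt), TRUE, probs)
      sel <- choice != "none"
      if (any(sel)) {
        st <- round(runif(sum(sel), 0, 4))
        dur <- ifelse(choice[sel] == "een", round(runif(sum(sel), 42, 56)),
                      ifelse(choice[sel] == "corticosteroid",
                             round(runif(sum(sel), 45, 80)),
                             round(runif(sum(sel), 90, 200))))
        add(id[untrt[sel]], choice[sel], st, pmin(st + dur,
                                                  ifelse(choice[sel] == "corticosteroid", 88, Inf)))
      }
    }
    imm <- which(runif(n) < tj$imm_prob)
    if (length(imm)) {
      add(id[imm], "immunomodulator", round(runif(length(imm), 0, 30)),
          NA_real_)
    }
    ## steroid failure mode: a course overlapping the steroid-free window
    stmode <- which(!y & mode == "steroid")
    if (length(stmode)) {
      st <- round(runif(length(stmode), 95, 250))
      add(id[stmode], "corticosteroid", st,
          st + round(runif(length(stmode), 30, 60)))
    }
    ## treatment intensification: arm-specific escalation or luminal surgery
    events <- list()
    inmode <- which(!y & mode == "intens")
    intens_day <- rep(NA_real_, n)
    if (length(inmode)) {
      d <- round(runif(length(inmode), 120, 350))
      intens_day[inmode] <- d
      p_surg <- ifelse(a[inmode], tj$surgery_given_intens["early"],
                       tj$surgery_given_intens["noearly"])
      surg <- runif(length(inmode)) < p_surg
      if (any(surg)) {
        events[[length(events) + 1L]] <- tibble(
          id = id[inmode[surg]], day = d[surg], kind = "luminal_resection")
      }
      esc <- inmode[!surg]
      if (length(esc)) {
        agent <- ifelse(a[esc],
                        sample(SECOND_LINE_AGENTS, length(esc), TRUE),
                        sample(ANTITNF_AGENTS, length(esc), TRUE,
                               c(0.55, 0.45)))
        add(id[esc], agent, d[!surg], NA_real_)
      }
    }
    ## benign non-luminal procedures (never treatment escalation)
    oth <- which(runif(n) < 0.02)
    if (length(oth)) {
      events[[length(events) + 1L]] <- tibble(
        id = id[oth], day = round(runif(length(oth), 30, 350)), kind = "other")
    }
    therapies <- if (length(ther)) dplyr::bind_rows(ther) else NULL
    events <- if (length(events)) dplyr::bind_rows(events) else
      tibble(id = character(0), day = numeric(0), kind = character(0))

    ## --- anthropometrics and HRQOL at months 0 / 12 / 24 ----------------
    arm <- ifelse(a, "early", "noearly")
    z_hfa_12 <- cov$hfa_z + rnorm(n, tj$delta_hfa_1y[arm], tj$delta_hfa_1y_sd[arm])
    z_bmi_12 <- cov$bmi_z + rnorm(n, tj$delta_bmi_1y[arm], tj$delta_bmi_1y_sd[arm])
    z_hfa_24 <- cov$hfa_z + rnorm(n, tj$delta_hfa_2y[arm], tj$delta_hfa_2y_sd[arm])
    z_bmi_24 <- cov$bmi_z + rnorm(n, tj$delta_bmi_2y[arm], tj$delta_bmi_2y_sd[arm])
    anthro <- function(z_h, z_b, age_months) {
      ## clamp to the clinically plausible band; keeps the Box-Cox
      ## inversion well-defined for strongly skewed BMI references
      z_h <- pmin(4, pmax(-4, z_h))
      z_b <- pmin(4, pmax(-4, z_b))
      lh <- lms_lookup(ref, cov$sex, "height_for_age", age_months)
      lb <- lms_lookup(ref, cov$sex, "bmi_for_age", age_months)
      height <- lms_inverse(z_h, lh[, "L"], lh[, "M"], lh[, "S"])
      bmi <- lms_inverse(z_b, lb[, "L"], lb[, "M"], lb[, "S"])
      list(height = round(height, 1),
           weight = round(bmi * (height / 100)^2, 1))
    }
    age_m0 <- cov$age_years * 12
    a0 <- anthro(cov$hfa_z, cov$bmi_z, age_m0)
    a12 <- anthro(z_hfa_12, z_bmi_12, age_m0 + day12 / 30.4375)
    a24 <- if ("m24" %in% colnames(daym)) {
      anthro(z_hfa_24, z_bmi_24, age_m0 + daym[, "m24"] / 30.4375)
    } else {
      NULL
    }
    impact0 <- pmin(100, pmax(0, round(rnorm(n, 62, 13), 1)))
    vas0 <- pmin(100, pmax(0, round(rnorm(n, 55, 18))))
    impact12 <- round(pmin(100, pmax(0, impact0 +
                                       rnorm(n, tj$delta_impact3[arm],
                                             tj$delta_impact3_sd))), 1)
    vas12 <- round(pmin(100, pmax(0, vas0 + rnorm(n, tj$delta_vas[arm],
                                                  tj$delta_vas_sd))))

    ## --- visit rows -----------------------------------------------------
    crp_ml <- c(remission = log(0.25), mild = log(0.9), moderate = log(2.5),
                severe = log(4))
    fcp_ml <- c(remission = log(140), mild = log(400), moderate = log(900),
                severe = log(1100))
    mini_mu <- c(remission = 1.9, mild = 4.5, moderate = 7, severe = 9)
    vlist <- list(tibble(
      id = id, nominal_month = 0, day = 0,
      wpcdai = cov$wpcdai,
      pga = categorize_activity(cov$wpcdai),
      crp = cov$crp, fcp = cov$fcp, mini_index = NA_real_,
      height_cm = a0$height, weight_kg = a0$weight,
      impact3_total = impact0, eq5d_vas = vas0))
    for (j in seq_along(fmonths)) {
      mth <- fmonths[j]
      cat_j <- catm[, j]
      w <- wpcdai_for_category(cat_j)
      vlist[[length(vlist) + 1L]] <- tibble(
        id = id, nominal_month = mth, day = daym[, j],
        wpcdai = w, pga = cat_j,
        crp = round(rlnorm(n, crp_ml[cat_j], 0.7), 2),
        fcp = round(rlnorm(n, fcp_ml[cat_j], 0.8), 1),
        mini_index = if (mth %in% c(12, 24))
          round(pmax(0, rnorm(n, mini_mu[cat_j], 1.6)), 1) else NA_real_,
        height_cm = if (mth == 12) a12$height else if (mth == 24 &&
          !is.null(a24)) a24$height else NA_real_,
        weight_kg = if (mth == 12) a12$weight else if (mth == 24 &&
          !is.null(a24)) a24$weight else NA_real_,
        impact3_total = if (mth == 12) impact12 else NA_real_,
        eq5d_vas = if (mth == 12) vas12 else NA_real_)
    }
    visits <- dplyr::bind_rows(vlist)

    ## --- baseline table -------------------------------------------------
    ulcers <- matrix("none", n, length(ULCER_COLS),
                     dimnames = list(NULL, ULCER_COLS))
    nonile <- sample(c("none", "aphthous"), n * 4L, TRUE, c(0.6, 0.4))
    ulcers[, COLONIC_ULCER_COLS] <- nonile
    ulcers[, "ulcer_ileum"] <- sample(c("none", "aphthous", "large"), n, TRUE,
                                      c(0.5, 0.35, 0.15))
    di <- which(cov$deep_colonic_ulcers)
    if (length(di)) {
      seg <- sample(COLONIC_ULCER_COLS, length(di), TRUE)
      sz <- sample(c("large", "very_large"), length(di), TRUE, c(0.7, 0.3))
      ulcers[cbind(di, match(seg, ULCER_COLS))] <- sz
    }
    last_day <- apply(daym, 1L, max) + round(runif(n, 30, 200))
    baseline <- tibble(
      id = id, age_years = round(cov$age_years, 2), sex = cov$sex,
      time_to_diagnosis_days = cov$time_to_diagnosis_days,
      crp = cov$crp, esr = cov$esr, fcp = cov$fcp,
      wpcdai = cov$wpcdai, pga = categorize_activity(cov$wpcdai),
      sescd_total = cov$sescd_total)
    baseline <- cbind(baseline, as_tibble(as.data.frame(ulcers,
                                                        stringsAsFactors = FALSE)))
    baseline <- as_tibble(cbind(baseline, tibble(
      paris_location = cov$paris_location, upper_gi = cov$upper_gi,
      behaviour = cov$behaviour,
      b1_narrowing_no_dilatation = cov$b1_narrowing_no_dilatation,
      perianal = cov$perianal,
      height_cm = a0$height, weight_kg = a0$weight,
      last_followup_day = last_day,
      dropout_before_1y = runif(n) < config$dropout_rate)))

    ## --- bookkeeping truth labels at both horizons ----------------------
    sus <- function(h, ok_levels) {
      cols <- which(fmonths >= 3 & fmonths <= h)
      apply(catm[, cols, drop = FALSE], 1L,
            function(r) all(r %in% ok_levels))
    }
    steroid_ok <- !(!y & mode == "steroid")
    intens_ok <- !(!y & mode == "intens")
    truth <- tibble(
      id = id, a = a, p0 = mech$p0, p1 = mech$p1,
      y0 = mech$y0, y1 = mech$y1,
      ssfmi_star0 = mech$ssfmi0, ssfmi_star1 = mech$ssfmi1,
      mode = mode,
      ssfr_12 = sus(12, "remission") & steroid_ok,
      ssfr_star_12 = sus(12, "remission") & steroid_ok & intens_ok,
      ssfmi_12 = sus(12, c("remission", "mild")) & steroid_ok,
      ssfmi_star_12 = sus(12, c("remission", "mild")) & steroid_ok & intens_ok,
      ssfr_star_24 = if (24 %in% fmonths)
        sus(24, "remission") & steroid_ok & intens_ok else NA,
      ssfmi_star_24 = if (24 %in% fmonths)
        sus(24, c("remission", "mild")) & steroid_ok & intens_ok else NA)
    stopifnot(identical(truth$ssfr_star_12, y))

    cohort <- cd_cohort(baseline, visits, therapies, events)
    list(cohort = cohort, truth = truth)
  })

  complete <- built$cohort
  out <- inject_missingness(complete, config, seed = seeds[2])
  attr(out, "truth") <- built$truth
  attr(out, "complete") <- complete
  out
}

#' Truth table of a simulated cohort
#'
#' @param cohort a cohort produced by [simulate_cohort()].
#' @return the generator's truth tibble (potential outcomes, failure modes,
#'   bookkeeping outcome labels).
#' @export
cohort_truth <- function(cohort) {
  attr(cohort, "truth")
}

#' Inject missingness into a complete cohort
#'
#' Applies per-variable Bernoulli deletion to the baseline and visit tables:
#' independent rates per column, a joint "endoscopy block" deletion (SES-CD
#' total and all ulcer sub-scores together), a joint visit "status" deletion
#' (wPCDAI and PGA together, making the visit's activity unevaluable), and
#' optionally missing-at-random faecal calprotectin whose deletion log-odds
#' increase with the observed wPCDAI. The input (complete) cohort is
#' attached as `attr(, "complete")`.
#'
#' @param cohort a [cd_cohort].
#' @param config a [sim_config()] (its `missingness` component is used).
#' @param seed integer seed.
#' @return the cohort with missingness applied.
#' @export
inject_missingness <- function(cohort, config, seed = 1L) {
  stopifnot(inherits(cohort, "cd_cohort"))
  ms <- config$missingness
  check_prob(c(ms$baseline, ms$visits, ms$endoscopy_block), "missingness rate")
  out <- with_seed(seed, {
    b <- cohort$baseline
    v <- cohort$visits
    del <- function(x, p) { x[runif(length(x)) < p] <- NA; x }
    for (nm in names(ms$baseline)) {
      if (nm %in% names(b)) b[[nm]] <- del(b[[nm]], ms$baseline[[nm]])
    }
    if (ms$endoscopy_block > 0) {
      gone <- runif(nrow(b)) < ms$endoscopy_block
      for (nm in c("sescd_total", ULCER_COLS)) b[[nm]][gone] <- NA
    }
    rates <- ms$visits
    if ("status" %in% names(rates) && rates[["status"]] > 0) {
      gone <- runif(nrow(v)) < rates[["status"]]
      v$wpcdai[gone] <- NA
      v$pga[gone] <- NA
    }
    mar_coef <- ms$mar$fcp_on_wpcdai %||% 0
    for (nm in setdiff(names(rates), "status")) {
      if (!nm %in% names(v)) next
      p <- rates[[nm]]
      if (nm == "fcp" && mar_coef != 0) {
        sev <- (ifelse(is.na(v$wpcdai), 30, v$wpcdai) - 30) / 20
        pvec <- plogis(qlogis(p) + mar_coef * sev)
        v[[nm]][runif(nrow(v)) < pvec] <- NA
      } else {
        v[[nm]] <- del(v[[nm]], p)
      }
    }
    ## never delete the baseline visit's day/identity columns
    cd_cohort(b, v, cohort$therapies, cohort$events, validate = FALSE)
  })
  attr(out, "complete") <- cohort
  out
}
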
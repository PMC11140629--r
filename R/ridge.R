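## ----------------------------------------------------------------------------
## Ridge-penalised logistic regression via penalised IRLS, model-based
## standardisation (g-computation) to marginal RR/OR/RD, bootstrap variance,
## and pooling across multiply-imputed datasets.
## ----------------------------------------------------------------------------

#' Model specification for the causal analysis
#'
#' Names the outcome flag, the binary treatment column, and the confounder
#' set entering the penalised outcome model. The default confounders are the
#' pre-specified clinical set: age at diagnosis, sex, moderate-to-severe
#' disease activity, CRP, and the five predictors of poor outcome.
#'
#' @param outcome outcome column name (e.g. `"ssfr_star"`).
#' @param treatment treatment column name (binary/logical).
#' @param covariates character vector of confounder column names.
#' @param lambda ridge penalty weight (>= 0). The default 0.125 corresponds
#'   to a Gaussian prior with standard deviation 2 on each standardised
#'   coefficient (`lambda = 1 / (2 * sigma^2)`).
#' @param penalize_treatment should the treatment coefficient be penalised
#'   like the confounders (default `TRUE`)? Turning this off changes the
#'   estimand's shrinkage behaviour; use deliberately.
#' @param standardize_covariates centre/scale continuous covariates to unit
#'   variance before penalisation (coefficients are reported back on the
#'   original scale).
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(outcome = "ssfr_star",
                       treatment = "early_antitnf",
                       covariates = c("age_years", "sex",
                                      "moderate_severe_activity", "crp",
                                      "perianal", "deep_colonic_ulcers",
                                      "extensive_disease", "growth_delay",
                                      "complicated_disease"),
                       lambda = 0.125,
                       penalize_treatment = TRUE,
                       standardize_covariates = TRUE) {
  if (anyDuplicated(covariates)) stop("covariates must be distinct", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(outcome = outcome, treatment = treatment,
                 covariates = covariates, lambda = lambda,
                 penalize_treatment = penalize_treatment,
                 standardize_covariates = standardize_covariates),
            class = "model_spec")
}

## build (y, X) from a data frame and a spec; treatment becomes column 1 of X
build_design <- function(data, spec, drop_constant = FALSE) {
  stopifnot(all(c(spec$outcome, spec$treatment, spec$covariates) %in%
                  names(data)))
  y <- as.numeric(data[[spec$outcome]])
  trt <- as.numeric(data[[spec$treatment]])
  covs <- data[, spec$covariates, drop = FALSE]
  covs[] <- lapply(covs, function(col) {
    if (is.character(col)) factor(col) else col
  })
  mm <- stats::model.matrix(~ ., data = covs)[, -1L, drop = FALSE]
  if (drop_constant) {
    const <- apply(mm, 2L, function(col) length(unique(col)) == 1L)
    if (any(const)) {
      warning("dropping constant covariate column(s): ",
              paste(colnames(mm)[const], collapse = ", "), call. = FALSE)
      mm <- mm[, !const, drop = FALSE]
    }
  }
  x <- cbind(treatment = trt, mm)
  list(y = y, x = x)
}

## penalised IRLS core on a prepared design (first column must be intercept).
## d: per-column penalty weights (0 for intercept). Returns beta and the final
## penalised Hessian's Cholesky factor for posterior-style draws.
ridge_irls <- function(X, y, d, beta = NULL, max_iter = 50L, tol = 1e-9) {
  p <- ncol(X)
  if (is.null(beta)) {
    beta <- numeric(p)
    pbar <- min(max(mean(y), 1e-3), 1 - 1e-3)
    beta[1L] <- qlogis(pbar)
  }
  penloglik <- function(b, eta) sum(y * eta - log1pexp(eta)) - sum(d * b^2)
  eta <- drop(X %*% beta)
  f <- penloglik(beta, eta)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - 2 * d * beta
    H <- crossprod(X, X * w)
    diag(H) <- diag(H) + 2 * d
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    ## step-halving line search on the penalised log-likelihood
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      eta_new <- drop(X %*% beta_new)
      f_new <- penloglik(beta_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new; eta <- eta_new
    improved <- f_new - f
    f <- f_new
    if (moved < tol || (it > 1L && improved < 1e-12 && max(abs(grad)) <
                          1e-6 * max(1, length(y)))) {
      mu <- plogis(eta)
      grad <- drop(crossprod(X, y - mu)) - 2 * d * beta
      converged <- max(abs(grad)) < 1e-5 * max(1, length(y))
      break
    }
  }
  if (converged && max(abs(beta)) > 30 && all(d == 0)) converged <- FALSE
  list(beta = beta, converged = converged, loglik = f + sum(d * beta^2),
       penloglik = f, hessian = H)
}

#' Fit a ridge-penalised logistic regression
#'
#' Maximises the binomial log-likelihood minus `lambda * sum(beta_j^2)` over
#' the penalised coefficients (all non-intercept columns by default) by
#' iteratively reweighted least squares with step-halving. The penalty is the
#' log-density of a mean-zero Gaussian prior, which keeps coefficients finite
#' even under complete separation. With `lambda = 0` the fit reduces to
#' ordinary maximum likelihood and refuses to return silently under
#' separation (non-convergence error).
#'
#' @param x numeric design matrix *without* an intercept column (the
#'   intercept is added internally and never penalised).
#' @param y binary outcome vector (0/1 or logical); both classes required.
#' @param lambda ridge penalty weight (>= 0).
#' @param penalize logical vector, one per column of `x`: penalise this
#'   coefficient? Default all `TRUE`.
#' @param standardize centre and scale continuous columns (more than two
#'   distinct values) to unit variance before penalisation; coefficients are
#'   back-transformed to the original scale.
#' @param start optional start values on the internal (standardised) scale.
#' @param max_iter,tol IRLS controls.
#' @return an object of class `ridge_fit`: `coefficients` (named, original
#'   scale, intercept first), `beta0`, `beta_treatment` (the column named
#'   `"treatment"`, if present), `lambda_used`, `converged`, `n_used`,
#'   `loglik`, plus internal scaling info for fast refits.
#' @export
fit_ridge_logistic <- function(x, y, lambda = 0.125, penalize = NULL,
                               standardize = TRUE, start = NULL,
                               max_iter = 50L, tol = 1e-9) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("outcome has a single class; cannot fit", call. = FALSE)
  }
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (is.null(penalize)) penalize <- rep(TRUE, ncol(x))
  stopifnot(length(penalize) == ncol(x))

  center <- rep(0, ncol(x))
  scale_ <- rep(1, ncol(x))
  if (standardize) {
    for (j in seq_len(ncol(x))) {
      vals <- unique(x[, j])
      if (length(vals) > 2L) {
        center[j] <- mean(x[, j])
        s <- sd(x[, j])
        if (s > 0) scale_[j] <- s
      }
    }
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  X <- cbind(`(Intercept)` = 1, xs)
  d <- c(0, lambda * as.numeric(penalize))

  fit <- ridge_irls(X, y, d, beta = start, max_iter = max_iter, tol = tol)
  if (!fit$converged && lambda == 0) {
    stop("unpenalised logistic fit did not converge (possible separation); ",
         "use lambda > 0", call. = FALSE)
  }
  beta_s <- fit$beta
  beta <- beta_s
  beta[-1L] <- beta_s[-1L] / scale_
  beta[1L] <- beta_s[1L] - sum(beta_s[-1L] * center / scale_)
  names(beta) <- c("(Intercept)", colnames(x))

  structure(list(
    coefficients = beta,
    beta0 = unname(beta[1L]),
    beta_treatment = if ("treatment" %in% colnames(x))
      unname(beta["treatment"]) else NA_real_,
    beta_covariates = beta[setdiff(names(beta), c("(Intercept)", "treatment"))],
    lambda_used = lambda,
    converged = fit$converged,
    n_used = length(y),
    loglik = fit$loglik,
    beta_internal = beta_s,
    center = center, scale = scale_, penalize = penalize
  ), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("<ridge_fit> n = %d, lambda = %g, converged = %s\n",
              x$n_used, x$lambda_used, x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted risks from a ridge fit
#'
#' @param object a `ridge_fit`.
#' @param newx design matrix with the same columns the fit was given.
#' @param ... unused.
#' @return vector of predicted probabilities.
#' @export
predict.ridge_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  drop(plogis(cbind(1, newx) %*% object$coefficients))
}

#' Construct a ridge_fit from known coefficients
#'
#' Builds a minimal fit object around externally supplied coefficients, for
#' standardising a model whose parameters are fixed by hand (e.g. exact toy
#' examples).
#'
#' @param coefficients named vector, `"(Intercept)"` first, one entry per
#'   design column; the treatment coefficient must be named `"treatment"`.
#' @return a `ridge_fit`.
#' @export
as_ridge_fit <- function(coefficients) {
  structure(list(coefficients = coefficients,
                 beta0 = unname(coefficients[1L]),
                 beta_treatment = unname(coefficients["treatment"]),
                 beta_covariates = coefficients[setdiff(names(coefficients),
                                                        c("(Intercept)", "treatment"))],
                 lambda_used = NA_real_, converged = TRUE,
                 n_used = NA_integer_, loglik = NA_real_),
            class = "ridge_fit")
}

#' Model-based standardisation to marginal effects
#'
#' Implements regression standardisation (g-computation): the fitted outcome
#' model is evaluated twice on the observed covariate distribution, once
#' with treatment set to 1 for everyone and once with 0 for everyone; the
#' means of the predicted risks are the standardised marginal risks
#' `p_bar_1` and `p_bar_0`, from which the marginal risk ratio, odds ratio
#' and risk difference follow. Under no unmeasured confounding these are the
#' population causal contrasts an arm-randomised experiment would target.
#'
#' @param fit a `ridge_fit` whose design had the treatment in a column named
#'   `"treatment"`.
#' @param x design matrix (same columns as the fit, treatment included; the
#'   treatment column's observed values are ignored).
#' @return list of class `standardized_effect`: `p_bar_1`, `p_bar_0`, `rr`,
#'   `or`, `rd`.
#' @export
standardize <- function(fit, x) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty dataset", call. = FALSE)
  stopifnot("treatment" %in% colnames(x))
  x1 <- x; x1[, "treatment"] <- 1
  x0 <- x; x0[, "treatment"] <- 0
  p1 <- mean(predict(fit, x1))
  p0 <- mean(predict(fit, x0))
  structure(list(p_bar_1 = p1, p_bar_0 = p0,
                 rr = p1 / p0,
                 or = (p1 / (1 - p1)) / (p0 / (1 - p0)),
                 rd = p1 - p0),
            class = "standardized_effect")
}

#' @export
print.standardized_effect <- function(x, ...) {
  cat(sprintf("<standardized_effect> p1 = %.4f, p0 = %.4f, RR = %.3f, OR = %.3f, RD = %.4f\n",
              x$p_bar_1, x$p_bar_0, x$rr, x$or, x$rd))
  invisible(x)
}

#' Bootstrap the standardised effect
#'
#' Nonparametric patient-level bootstrap of the full estimator: resample
#' subjects with replacement, refit the penalised model on each resample
#' (warm-started from the full-data fit, reusing its covariate scaling), and
#' re-standardise *within the resample*. The point estimate is the full-data
#' estimate; the variance is the sample variance of the replicate log
#' effects. Replicates that fail to converge (or produce a degenerate risk)
#' are dropped and counted; more than 10% failures warns, more than 50%
#' errors.
#'
#' @param data data frame with the spec's columns, or `NULL` when `x`/`y`
#'   are given directly.
#' @param spec a [model_spec()].
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed; the summary is reproducible given it.
#' @param x,y optional prebuilt design (treatment in column
#'   `"treatment"`) and outcome, bypassing `data`.
#' @return list of class `bootstrap_summary`: per scale (`log_rr`, `log_or`,
#'   `rd`) the full-data `point` and bootstrap `variance`; plus `n_reps`,
#'   `failures`, the full-data `effect` (a `standardized_effect`) and `fit`.
#' @export
bootstrap_effect <- function(data = NULL, spec = model_spec(), n_reps = 1000,
                             seed = 1L, x = NULL, y = NULL) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (is.null(x)) {
    des <- build_design(data, spec, drop_constant = TRUE)
    x <- des$x; y <- des$y
  }
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- as.matrix(x)[keep, , drop = FALSE]
  y <- as.numeric(y)[keep]
  n <- length(y)
  penalize <- rep(TRUE, ncol(x))
  if (!spec$penalize_treatment) penalize[colnames(x) == "treatment"] <- FALSE

  full <- fit_ridge_logistic(x, y, lambda = spec$lambda, penalize = penalize,
                             standardize = spec$standardize_covariates)
  eff <- standardize(full, x)

  ## prebuild the standardised design once; counterfactual predictions only
  ## need the treatment column's two standardised values
  xs <- sweep(sweep(x, 2L, full$center), 2L, full$scale, "/")
  X <- cbind(1, xs)
  tcol <- which(colnames(x) == "treatment") + 1L
  d <- c(0, spec$lambda * as.numeric(penalize))
  beta_full <- full$beta_internal

  v1 <- (1 - full$center[tcol - 1L]) / full$scale[tcol - 1L]
  v0 <- (0 - full$center[tcol - 1L]) / full$scale[tcol - 1L]
  idx <- with_seed(seed,
                   matrix(sample.int(n, n * n_reps, replace = TRUE), n, n_reps))
  reps <- boot_replicates_cpp(X, y, d, beta_full, idx - 1L, tcol - 1L,
                              v1, v0, 30L, 1e-8)
  colnames(reps) <- c("log_rr", "log_or", "rd")
  failures <- sum(!stats::complete.cases(reps))
  if (failures > 0.5 * n_reps) {
    stop("more than half of bootstrap replicates failed", call. = FALSE)
  }
  if (failures > 0.1 * n_reps) {
    warning(sprintf("%d of %d bootstrap replicates failed", failures, n_reps),
            call. = FALSE)
  }
  ok <- stats::complete.cases(reps)
  structure(list(
    point = c(log_rr = log(eff$rr), log_or = log(eff$or), rd = eff$rd),
    variance = apply(reps[ok, , drop = FALSE], 2L, var),
    n_reps = n_reps, failures = failures,
    effect = eff, fit = full, n = n
  ), class = "bootstrap_summary")
}

#' Pooled causal effect across multiply-imputed datasets
#'
#' Runs the fit/standardise/bootstrap estimator within each completed
#' dataset, then pools the per-imputation log-scale points and bootstrap
#' variances with Rubin's rules ([pool_rubin()]) and exponentiates back.
#' Ratio effects are pooled on the log scale; two-sided p-values come from
#' the pooled t statistic with Barnard-Rubin degrees of freedom.
#'
#' @param datasets a list of completed data frames (e.g.
#'   [complete_all()] of an imputed stack), or a single data frame.
#' @param spec a [model_spec()].
#' @param n_reps bootstrap replicates per imputed dataset.
#' @param seed master seed; per-imputation substreams are derived from it.
#' @param confidence interval coverage (default 0.95).
#' @return a tibble with one row per scale (`rr`, `or`, `rd`): `estimate`,
#'   `ci_low`, `ci_high`, `p_value`, `q_bar`, `t_total`, `df`, `m`, plus
#'   attributes `per_imputation` (points/variances) and `p_bar` (pooled
#'   standardised risks).
#' @export
estimate_pooled <- function(datasets, spec = model_spec(), n_reps = 1000,
                            seed = 1L, confidence = 0.95) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  m <- length(datasets)
  seeds <- substream_seeds(seed, m)
  boots <- vector("list", m)
  for (i in seq_len(m)) {
    boots[[i]] <- bootstrap_effect(datasets[[i]], spec, n_reps = n_reps,
                                   seed = seeds[i])
  }
  points <- t(vapply(boots, function(b) b$point, numeric(3L)))
  vars <- t(vapply(boots, function(b) b$variance, numeric(3L)))
  p1s <- vapply(boots, function(b) b$effect$p_bar_1, numeric(1L))
  p0s <- vapply(boots, function(b) b$effect$p_bar_0, numeric(1L))

  pool_one <- function(scale_name, log_scale) {
    est <- points[, scale_name]
    vv <- vars[, scale_name]
    if (m == 1L) {
      se <- sqrt(vv)
      zq <- stats::qnorm(1 - (1 - confidence) / 2)
      ci <- est + c(-1, 1) * zq * se
      p <- 2 * stats::pnorm(-abs(est / se))
      out <- tibble(estimate = est, ci_low = ci[1], ci_high = ci[2],
                    p_value = p, q_bar = est, t_total = vv, df = Inf, m = m)
    } else {
      pr <- pool_rubin(est, vv, confidence = confidence)
      out <- tibble(estimate = pr$q_bar, ci_low = pr$ci_low,
                    ci_high = pr$ci_high, p_value = pr$p_value,
                    q_bar = pr$q_bar, t_total = pr$t_total, df = pr$df, m = m)
    }
    if (log_scale) {
      out$estimate <- exp(out$estimate)
      out$ci_low <- exp(out$ci_low)
      out$ci_high <- exp(out$ci_high)
    }
    out
  }
  res <- rbind(cbind(tibble(scale = "rr"), pool_one("log_rr", TRUE)),
               cbind(tibble(scale = "or"), pool_one("log_or", TRUE)),
               cbind(tibble(scale = "rd"), pool_one("rd", FALSE)))
  res <- as_tibble(res)
  attr(res, "per_imputation") <- list(points = points, variances = vars)
  attr(res, "p_bar") <- c(p_bar_1 = mean(p1s), p_bar_0 = mean(p0s))
  attr(res, "failures") <- sum(vapply(boots, function(b) b$failures, integer(1L)))
  res
}

#' Subgroup (risk-stratified) pooled effects
#'
#' Re-runs the pooled estimation within clinically pre-specified strata:
#' `"activity"` splits on baseline moderate-to-severe disease activity
#' (low-risk = mild/inactive), `"popo"` on the presence of any predictor of
#' poor outcome. Covariates that are constant within a stratum (the
#' stratifier itself; the POPO flags in the no-POPO stratum) are dropped
#' from the within-stratum model. Strata are formed within each imputed
#' dataset (stratum membership can differ across imputations when the
#' stratifier was itself imputed).
#'
#' @param datasets list of completed data frames.
#' @param spec a [model_spec()].
#' @param stratifier `"activity"` or `"popo"`.
#' @param n_reps,seed,confidence as in [estimate_pooled()].
#' @param min_n warn when a stratum has fewer subjects than this (default 25).
#' @return named list of per-stratum results (tibbles as in
#'   [estimate_pooled()]), `NULL` for an empty stratum.
#' @export
subgroup_estimates <- function(datasets, spec = model_spec(),
                               stratifier = c("activity", "popo"),
                               n_reps = 1000, seed = 1L, confidence = 0.95,
                               min_n = 25L) {
  stratifier <- match.arg(stratifier)
  if (is.data.frame(datasets)) datasets <- list(datasets)
  strat_col <- switch(stratifier, activity = "moderate_severe_activity",
                      popo = "any_popo")
  popo_cols <- c("perianal", "deep_colonic_ulcers", "extensive_disease",
                 "growth_delay", "complicated_disease")
  out <- list()
  for (high in c(FALSE, TRUE)) {
    label <- if (stratifier == "activity") {
      if (high) "moderate_severe" else "mild_inactive"
    } else {
      if (high) "any_popo" else "no_popo"
    }
    sub <- lapply(datasets, function(df) {
      strat <- if (strat_col %in% names(df)) {
        df[[strat_col]]
      } else if (stratifier == "popo") {
        apply(df[, popo_cols], 1L, tri_any)
      } else {
        stop("stratifier column not found: ", strat_col, call. = FALSE)
      }
      df[which(strat == high), , drop = FALSE]
    })
    ns <- vapply(sub, nrow, integer(1L))
    if (any(ns == 0L)) { out[[label]] <- NULL; next }
    if (any(ns < min_n)) {
      warning(sprintf("stratum '%s' has fewer than %d subjects", label, min_n),
              call. = FALSE)
    }
    sspec <- spec
    drop_covs <- if (stratifier == "activity") {
      strat_col
    } else if (!high) {
      popo_cols  # identically FALSE in the no-POPO stratum
    } else {
      character(0)
    }
    sspec$covariates <- setdiff(spec$covariates, drop_covs)
    res <- tryCatch(
      suppressWarnings(estimate_pooled(sub, sspec, n_reps = n_reps,
                                       seed = seed, confidence = confidence)),
      error = function(e) NULL)
    out[[label]] <- res
  }
  out
}
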
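## ----------------------------------------------------------------------------
## Multiple imputation by chained equations: predictive-mean matching for
## continuous variables, Bayesian logistic draws for binaries, polytomous
## regression for categoricals; plus Rubin's-rules pooling.
## ----------------------------------------------------------------------------

## Bayesian linear regression draw (coefficients and residual variance) with
## a tiny ridge on the cross-product for numerical stability.
norm_draw <- function(X, yobs) {
  p <- ncol(X)
  S <- crossprod(X)
  diag(S) <- diag(S) * (1 + 1e-5) + 1e-8
  Xty <- crossprod(X, yobs)
  R <- chol(S)
  beta_hat <- backsolve(R, forwardsolve(t(R), Xty))
  res <- yobs - drop(X %*% beta_hat)
  df <- max(length(yobs) - p, 1L)
  sigma2_star <- sum(res^2) / stats::rchisq(1L, df)
  beta_star <- beta_hat + sqrt(sigma2_star) * backsolve(R, rnorm(p))
  list(beta_hat = drop(beta_hat), beta_star = drop(beta_star))
}

## one PMM update: returns imputed values for the missing rows
impute_pmm <- function(Xobs, yobs, Xmis, k = 5L) {
  dr <- norm_draw(Xobs, yobs)
  yhat_obs <- drop(Xobs %*% dr$beta_hat)
  yhat_mis <- drop(Xmis %*% dr$beta_star)
  nobs <- length(yobs)
  k <- min(k, nobs)
  vapply(yhat_mis, function(yh) {
    dist <- abs(yhat_obs - yh)
    donors <- order(dist)[seq_len(k)]
    yobs[donors[sample.int(k, 1L)]]
  }, numeric(1L))
}

## one Bayesian-logistic update for a binary target
impute_logreg <- function(Xobs, yobs, Xmis) {
  d <- c(0, rep(1e-4, ncol(Xobs) - 1L))  # tiny ridge guards separation
  fit <- ridge_irls(Xobs, yobs, d, max_iter = 30L, tol = 1e-8)
  R <- chol(fit$hessian)
  beta_star <- fit$beta + backsolve(R, rnorm(length(fit$beta)))
  p <- plogis(drop(Xmis %*% beta_star))
  stats::runif(length(p)) < p
}

## one polytomous update via multinomial regression (no coefficient draw;
## categories are sampled from the fitted class probabilities)
impute_polyreg <- function(Xobs, yobs, Xmis) {
  dfo <- as.data.frame(Xobs[, -1L, drop = FALSE])
  dfm <- as.data.frame(Xmis[, -1L, drop = FALSE])
  yfac <- factor(yobs)
  fit <- nnet::multinom(yfac ~ ., data = cbind(dfo, yfac = yfac),
                        trace = FALSE, maxit = 200L)
  pr <- stats::predict(fit, newdata = dfm, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two classes
  lv <- levels(yfac)
  apply(pr, 1L, function(p) lv[sample.int(length(lv), 1L, prob = p)])
}

## build a numeric predictor design (intercept first) from the current data
predictor_design <- function(data, predictors) {
  covs <- data[, predictors, drop = FALSE]
  covs[] <- lapply(covs, function(col) {
    if (is.character(col)) factor(col) else if (is.logical(col))
      as.numeric(col) else col
  })
  mm <- stats::model.matrix(~ ., data = covs)
  const <- apply(mm[, -1L, drop = FALSE], 2L, function(c2) length(unique(c2)) == 1L)
  if (any(const)) mm <- mm[, c(TRUE, !const), drop = FALSE]
  mm
}

#' Multiple imputation by chained equations
#'
#' Fills the missing cells of an analysis dataset with `m` stochastic
#' completions by iterating univariate conditional models over the
#' incomplete variables (fully conditional specification): predictive-mean
#' matching (k donors) for continuous variables, Bayesian logistic draws for
#' binaries, and polytomous regression for factors with more than two
#' levels. Deterministic fills (e.g. the negative assumption for missing
#' perianal and complicated disease) must be applied *before* imputation.
#' Each of the `m` chains runs from its own substream seed, so completions
#' are mutually independent but jointly reproducible.
#'
#' @param data a data frame; columns of type numeric, logical, character or
#'   factor. All columns are used as predictors unless restricted.
#' @param m number of completed datasets (default 30).
#' @param iterations chained-equation cycles per dataset (default 10).
#' @param seed master seed.
#' @param methods optional named character vector overriding the per-variable
#'   method (`"pmm"`, `"logreg"`, `"polyreg"`).
#' @param predictors optional named list: for each imputed variable, the
#'   predictor columns to use (default: every other column).
#' @param exclude columns to leave out of the imputation entirely (neither
#'   imputed nor used as predictors), e.g. identifiers.
#' @param donors PMM donor-pool size (default 5).
#' @return an object of class `imputed_stack`: the original data, the
#'   missingness mask (`where`), the list of `m` completed datasets
#'   (`imputations`), per-variable/per-iteration chain means and SDs
#'   (`traces`), and the configuration. A non-convergence warning fires when
#'   a chain mean drifts more than half an SD between the last two
#'   iterations.
#' @export
chained_impute <- function(data, m = 30L, iterations = 10L, seed = 1L,
                           methods = NULL, predictors = NULL,
                           exclude = "id", donors = 5L) {
  stopifnot(is.data.frame(data), m >= 2L, iterations >= 1L)
  data <- as_tibble(data)
  work_cols <- setdiff(names(data), exclude)
  where <- is.na(data[, work_cols, drop = FALSE])
  targets <- work_cols[colSums(where) > 0L]

  for (v in targets) {
    if (all(is.na(data[[v]]))) {
      stop(sprintf("variable '%s' has no observed values; cannot impute", v),
           call. = FALSE)
    }
  }
  constant <- work_cols[vapply(work_cols, function(v) {
    obs <- data[[v]][!is.na(data[[v]])]
    length(unique(obs)) <= 1L
  }, logical(1L))]
  if (length(constant)) {
    warning("constant variable(s) dropped from the predictor set: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  method_of <- function(v) {
    if (!is.null(methods) && v %in% names(methods)) return(methods[[v]])
    col <- data[[v]]
    if (is.logical(col)) return("logreg")
    if (is.character(col) || is.factor(col)) {
      nl <- length(unique(col[!is.na(col)]))
      return(if (nl <= 2L) "logreg" else "polyreg")
    }
    "pmm"
  }
  vmethods <- vapply(targets, method_of, character(1L))
  ## impute in order of increasing missingness
  targets <- targets[order(colSums(where[, targets, drop = FALSE]))]
  vmethods <- vmethods[targets]

  if (!length(targets)) {
    imps <- replicate(m, data, simplify = FALSE)
    return(structure(list(data = data, where = where, imputations = imps,
                          traces = NULL, m = m, iterations = iterations,
                          seed = seed, methods = character(0)),
                     class = "imputed_stack"))
  }

  seeds <- substream_seeds(seed, m)
  imps <- vector("list", m)
  traces <- array(NA_real_, dim = c(length(targets), iterations, m, 2L),
                  dimnames = list(targets, NULL, NULL, c("mean", "sd")))

  for (im in seq_len(m)) {
    imps[[im]] <- with_seed(seeds[im], {
      cur <- data
      ## initial fill: random draws from the observed values
      for (v in targets) {
        miss <- is.na(cur[[v]])
        obs <- cur[[v]][!miss]
        cur[[v]][miss] <- sample(obs, sum(miss), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (vi in seq_along(targets)) {
          v <- targets[vi]
          miss <- is.na(data[[v]])
          preds <- if (!is.null(predictors) && v %in% names(predictors)) {
            predictors[[v]]
          } else {
            setdiff(work_cols, v)
          }
          mm <- predictor_design(cur, preds)
          Xobs <- mm[!miss, , drop = FALSE]
          Xmis <- mm[miss, , drop = FALSE]
          yobs <- data[[v]][!miss]
          newvals <- switch(vmethods[vi],
            pmm = impute_pmm(Xobs, as.numeric(yobs), Xmis, k = donors),
            logreg = {
              out <- impute_logreg(Xobs, as.numeric(yobs), Xmis)
              if (is.logical(data[[v]])) out else as.numeric(out)
            },
            polyreg = impute_polyreg(Xobs, yobs, Xmis),
            stop("unknown imputation method: ", vmethods[vi], call. = FALSE))
          cur[[v]][miss] <- newvals
          imputed <- cur[[v]][miss]
          num <- if (is.numeric(imputed) || is.logical(imputed)) {
            as.numeric(imputed)
          } else {
            as.numeric(factor(imputed, levels = sort(unique(data[[v]]))))
          }
          traces[vi, it, im, "mean"] <- mean(num)
          traces[vi, it, im, "sd"] <- sd(num)
        }
      }
      cur
    })
  }

  if (iterations >= 2L) {
    for (vi in seq_along(targets)) {
      mu_last <- mean(traces[vi, iterations, , "mean"])
      mu_prev <- mean(traces[vi, iterations - 1L, , "mean"])
      sd_last <- mean(traces[vi, iterations, , "sd"], na.rm = TRUE)
      if (is.finite(sd_last) && sd_last > 0 &&
          abs(mu_last - mu_prev) > 0.5 * sd_last) {
        warning(sprintf(paste0("imputation chain for '%s' may not have ",
                               "converged (mean drift %.2f SD between final ",
                               "iterations)"), targets[vi],
                        abs(mu_last - mu_prev) / sd_last), call. = FALSE)
      }
    }
  }

  structure(list(data = data, where = where, imputations = imps,
                 traces = traces, m = m, iterations = iterations,
                 seed = seed, methods = vmethods),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("<imputed_stack> m = %d, iterations = %d, %d variable(s) imputed\n",
              x$m, x$iterations, length(x$methods)))
  invisible(x)
}

#' Extract one completed dataset from an imputed stack
#'
#' @param stack an `imputed_stack`.
#' @param i which completion (1..m).
#' @return a tibble.
#' @export
complete_data <- function(stack, i = 1L) {
  stopifnot(inherits(stack, "imputed_stack"), i >= 1L, i <= stack$m)
  stack$imputations[[i]]
}

#' All completed datasets as a list
#'
#' @param stack an `imputed_stack`.
#' @return list of `m` tibbles.
#' @export
complete_all <- function(stack) {
  stopifnot(inherits(stack, "imputed_stack"))
  stack$imputations
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Combines `m` per-imputation point estimates and variances: the pooled
#' point is the mean; the total variance adds the mean within-imputation
#' variance and the between-imputation variance inflated by `(1 + 1/m)`;
#' degrees of freedom follow the Barnard-Rubin small-sample formula (with
#' `dfcom = Inf` this reduces to the classical `(m - 1) / lambda^2`).
#' Intervals are symmetric on the pooling scale — pool ratio estimates on
#' the log scale and exponentiate afterwards.
#'
#' @param estimates numeric vector of m point estimates (m >= 2).
#' @param variances numeric vector of m (non-negative) variances.
#' @param confidence interval coverage (default 0.95).
#' @param dfcom complete-data degrees of freedom (default `Inf`).
#' @return list of class `pooled_estimate`: `q_bar`, `u_bar`, `b_between`,
#'   `t_total`, `df`, `ci_low`, `ci_high`, `p_value`, `m`.
#' @examples
#' pool_rubin(c(1.0, 1.2, 1.4), c(0.04, 0.04, 0.04))$t_total  # 0.09333...
#' @export
pool_rubin <- function(estimates, variances, confidence = 0.95, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2L) stop("need at least two imputations to pool", call. = FALSE)
  if (length(variances) != m) {
    stop("'estimates' and 'variances' must have equal length", call. = FALSE)
  }
  if (any(variances < 0)) stop("variances must be non-negative", call. = FALSE)
  q_bar <- mean(estimates)
  u_bar <- mean(variances)
  b_between <- var(estimates)
  t_total <- u_bar + (1 + 1 / m) * b_between
  lambda <- (1 + 1 / m) * b_between / t_total
  if (!is.finite(lambda) || lambda <= 0) {
    df <- Inf
  } else {
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  se <- sqrt(t_total)
  tq <- if (is.finite(df)) stats::qt(1 - (1 - confidence) / 2, df) else
    stats::qnorm(1 - (1 - confidence) / 2)
  p_value <- if (se == 0) {
    ifelse(q_bar == 0, 1, 0)
  } else if (is.finite(df)) {
    2 * stats::pt(-abs(q_bar / se), df)
  } else {
    2 * stats::pnorm(-abs(q_bar / se))
  }
  structure(list(q_bar = q_bar, u_bar = u_bar, b_between = b_between,
                 t_total = t_total, df = df,
                 ci_low = q_bar - tq * se, ci_high = q_bar + tq * se,
                 p_value = p_value, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> q = %.4f [%.4f, %.4f], T = %.5f, df = %.1f, p = %.3g (m = %d)\n",
              x$q_bar, x$ci_low, x$ci_high, x$t_total, x$df, x$p_value, x$m))
  invisible(x)
}
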
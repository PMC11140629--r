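#' Compare a variable between two groups
#'
#' Applies the conventional descriptive-test selection rules: categorical
#' variables are compared with the chi-square test (no continuity
#' correction), switching to Fisher's exact test when any expected cell
#' count falls below 5; continuous variables with the two-sample t test when
#' both groups look approximately normal (Shapiro-Wilk p > 0.05 in both, and
#' at least 8 observations per group), otherwise the Mann-Whitney U test.
#' The choice made is reported alongside the result.
#'
#' @param values the variable (numeric, or character/factor/logical).
#' @param groups a two-level grouping vector of the same length.
#' @param kind `"auto"` (default: numeric means continuous),
#'   `"continuous"` or `"categorical"`.
#' @return a one-row tibble: `test_used`, `statistic`, `p_value`, and
#'   per-group `n`.
#' @export
compare_groups <- function(values, groups,
                           kind = c("auto", "continuous", "categorical")) {
  kind <- match.arg(kind)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required", call. = FALSE)
  n1 <- sum(groups == lv[1]); n2 <- sum(groups == lv[2])
  if (n1 == 0L || n2 == 0L) stop("one group is empty", call. = FALSE)
  if (kind == "auto") {
    kind <- if (is.numeric(values)) "continuous" else "categorical"
  }
  if (kind == "categorical") {
    tab <- table(groups, values)
    if (ncol(tab) < 2L) {
      return(tibble(test_used = "none", statistic = NA_real_, p_value = NA_real_,
                    n_group1 = n1, n_group2 = n2))
    }
    expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      return(tibble(test_used = "fisher_exact", statistic = NA_real_,
                    p_value = ft$p.value, n_group1 = n1, n_group2 = n2))
    }
    ct <- stats::chisq.test(tab, correct = FALSE)
    return(tibble(test_used = "chi_square",
                  statistic = unname(ct$statistic), p_value = ct$p.value,
                  n_group1 = n1, n_group2 = n2))
  }
  x1 <- values[groups == lv[1]]
  x2 <- values[groups == lv[2]]
  normal_ok <- function(x) {
    length(x) >= 8L && sd(x) > 0 && stats::shapiro.test(x)$p.value > 0.05
  }
  if (normal_ok(x1) && normal_ok(x2)) {
    tt <- stats::t.test(x1, x2)
    tibble(test_used = "t_test", statistic = unname(tt$statistic),
           p_value = tt$p.value, n_group1 = n1, n_group2 = n2)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x1, x2))
    tibble(test_used = "mann_whitney", statistic = unname(wt$statistic),
           p_value = wt$p.value, n_group1 = n1, n_group2 = n2)
  }
}

#' Outcome rate table by treatment arm
#'
#' Tabulates each tri-state outcome as events / evaluable denominator and
#' integer percentage per arm, plus the between-arm p-value (chi-square, or
#' Fisher when expected counts are small). Denominators count only patients
#' whose flag is definitively `TRUE` or `FALSE`; not-evaluable patients are
#' excluded, so denominators vary legitimately across outcomes. Percentages
#' are always recomputed from the events/denominator pair.
#'
#' @param flags outcome-flag tibble (e.g. from [derive_outcomes()]) with an
#'   `early_antitnf` column.
#' @param outcomes character vector of flag columns to tabulate (default:
#'   every logical flag except the exposure).
#' @return tibble: one row per outcome with `events_early`, `denom_early`,
#'   `pct_early`, `events_noearly`, `denom_noearly`, `pct_noearly`,
#'   `events_total`, `denom_total`, `pct_total`, `p_value`.
#' @export
outcome_table <- function(flags, outcomes = NULL) {
  stopifnot("early_antitnf" %in% names(flags))
  if (is.null(outcomes)) {
    outcomes <- names(flags)[vapply(flags, is.logical, logical(1L))]
    outcomes <- setdiff(outcomes, "early_antitnf")
  }
  arm <- flags$early_antitnf
  rows <- lapply(outcomes, function(oc) {
    x <- flags[[oc]]
    seg <- function(sel) {
      ev <- sum(x[sel], na.rm = TRUE)
      den <- sum(!is.na(x[sel]))
      c(events = ev, denom = den,
        pct = if (den > 0) round(100 * ev / den) else NA_real_)
    }
    e <- seg(arm %in% TRUE)
    ne <- seg(arm %in% FALSE)
    tot <- seg(rep(TRUE, length(x)))
    p <- if (e[["denom"]] > 0 && ne[["denom"]] > 0) {
      evaluable <- !is.na(x) & !is.na(arm)
      cg <- tryCatch(
        compare_groups(factor(x[evaluable], levels = c(FALSE, TRUE)),
                       arm[evaluable], kind = "categorical"),
        error = function(e2) NULL)
      if (is.null(cg)) NA_real_ else cg$p_value
    } else {
      NA_real_
    }
    tibble(outcome = oc,
           events_early = e[["events"]], denom_early = e[["denom"]],
           pct_early = e[["pct"]],
           events_noearly = ne[["events"]], denom_noearly = ne[["denom"]],
           pct_noearly = ne[["pct"]],
           events_total = tot[["events"]], denom_total = tot[["denom"]],
           pct_total = tot[["pct"]],
           p_value = p)
  })
  dplyr::bind_rows(rows)
}

pipeline_schema <- c("seed", "out_dir", "simulate", "cohort_files",
                     "outcomes", "impute", "estimate")

#' Run the full pipeline from a YAML configuration
#'
#' Orchestrates simulate (or read a cohort from CSV paths), derive outcomes,
#' impute, estimate and report, writing every artifact (cohort CSVs, the
#' per-patient outcome flags with tri-state columns encoded 1/0/NA, the
#' outcome rate table, pooled estimates, truth summaries for simulated
#' cohorts, and a manifest of seeds and parameters) into the output
#' directory. Reruns with the same configuration reproduce the same numbers.
#'
#' Configuration keys: `seed`; `out_dir`; either `simulate` (arguments to
#' [sim_config()]) or `cohort_files` (the four CSV paths); `outcomes`
#' (`horizon_month`); `impute` (`m`, `iterations`); `estimate` (`outcome`,
#' `n_reps`, `lambda`, `subgroup`). Unknown keys are rejected by name.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir overrides the configured output directory.
#' @return (invisibly) a list with the principal results and artifact paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(cfg), pipeline_schema)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory configured",
                                                call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    ## YAML 1.1 parses a bare `n:` key as a boolean; map it back
    names(sim_args)[names(sim_args) %in% c("FALSE", "no")] <- "n"
    sc <- do.call(sim_config, utils::modifyList(sim_args, list(seed = seed)))
    cohort <- simulate_cohort(sc)
    truth <- cohort_truth(cohort)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"), na = "")
    te <- true_marginal_effects(sc, n_mc = 1e5, seed = seed)
    jsonlite::write_json(unclass(te), file.path(out_dir, "true_effects.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (!is.null(cfg$cohort_files)) {
    cohort <- do.call(read_cohort, cfg$cohort_files)
  } else {
    stop("configuration needs either 'simulate' or 'cohort_files'",
         call. = FALSE)
  }

  horizon <- cfg$outcomes$horizon_month %||% 12
  flags <- derive_outcomes(analysis_set(cohort), horizon_month = horizon)
  enc <- flags
  enc[] <- lapply(enc, function(col) if (is.logical(col))
    as.integer(col) else col)
  readr::write_csv(enc, file.path(out_dir, "outcomes.csv"), na = "NA")
  tab <- outcome_table(flags)
  readr::write_csv(tab, file.path(out_dir, "outcome_table.csv"), na = "")

  est_cfg <- cfg$estimate %||% list()
  res <- estimate_effect(
    cohort,
    outcome = est_cfg$outcome %||% "ssfr_star",
    horizon_month = horizon,
    m = cfg$impute$m %||% 30L,
    iterations = cfg$impute$iterations %||% 10L,
    n_reps = est_cfg$n_reps %||% 1000L,
    lambda = est_cfg$lambda %||% 0.125,
    subgroup = est_cfg$subgroup %||% "none",
    seed = seed)
  readr::write_csv(res$estimates, file.path(out_dir, "estimates.csv"), na = "")
  jsonlite::write_json(
    list(estimates = res$estimates,
         subgroups = lapply(res$subgroups, function(s) s)),
    file.path(out_dir, "estimates.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")

  manifest <- list(
    seed = seed, horizon_month = horizon,
    m = cfg$impute$m %||% 30L, iterations = cfg$impute$iterations %||% 10L,
    n_reps = est_cfg$n_reps %||% 1000L,
    lambda = est_cfg$lambda %||% 0.125,
    outcome = est_cfg$outcome %||% "ssfr_star",
    simulated = !is.null(cfg$simulate),
    package_version = as.character(utils::packageVersion("earlytnf")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(outcome_table = tab, estimates = res$estimates,
                 subgroups = res$subgroups, truth = truth, out_dir = out_dir))
}
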
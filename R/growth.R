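LMS_METRICS <- c("height_for_age", "bmi_for_age")

#' LMS Z-score
#'
#' Standardises a measurement against an age- and sex-specific reference
#' summarised by the Box-Cox power (L), median (M) and coefficient of
#' variation (S): `z = ((x/M)^L - 1) / (L * S)` for `L != 0`, with the
#' limiting form `z = log(x/M) / S` when `|L|` is numerically zero.
#'
#' @param x measurement (> 0); vectorised, recycled against L/M/S.
#' @param L,M,S reference parameters (M > 0, S > 0).
#' @return numeric Z-scores.
#' @examples
#' lms_zscore(105, L = 1, M = 100, S = 0.05)  # exactly 1
#' @export
lms_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(x <= 0, na.rm = TRUE)) stop("'x' must be positive", call. = FALSE)
  if (any(M <= 0 | S <= 0, na.rm = TRUE)) {
    stop("'M' and 'S' must be positive", call. = FALSE)
  }
  z <- numeric(n)
  zero <- !is.na(L) & abs(L) < 1e-8
  z[zero] <- log(x[zero] / M[zero]) / S[zero]
  nz <- !zero
  z[nz] <- ((x[nz] / M[nz])^L[nz] - 1) / (L[nz] * S[nz])
  z[is.na(x) | is.na(L) | is.na(M) | is.na(S)] <- NA_real_
  z
}

#' Invert an LMS Z-score back to the measurement scale
#'
#' @param z Z-score.
#' @inheritParams lms_zscore
#' @return the measurement `x` with `lms_zscore(x, L, M, S) == z`.
#' @export
lms_inverse <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  out <- numeric(n)
  zero <- !is.na(L) & abs(L) < 1e-8
  out[zero] <- M[zero] * exp(S[zero] * z[zero])
  nz <- !zero
  out[nz] <- M[nz] * (1 + L[nz] * S[nz] * z[nz])^(1 / L[nz])
  out[is.na(z)] <- NA_real_
  out
}

#' Read an LMS reference table
#'
#' The schema is one row per `(sex, metric, age_months)` with columns
#' `sex` (`M`/`F`), `age_months`, `metric`
#' (`height_for_age` or `bmi_for_age`), `L`, `M`, `S`. Ages must be strictly
#' increasing within each sex/metric block, and M and S positive. The package
#' ships a synthetic reference of this schema for examples and tests
#' ([lms_reference_synthetic()]); users supply real growth-standard tables in
#' the same format.
#'
#' @param path CSV file path.
#' @return a validated tibble.
#' @export
read_lms_reference <- function(path) {
  ref <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(), age_months = readr::col_double(),
    metric = readr::col_character(), L = readr::col_double(),
    M = readr::col_double(), S = readr::col_double()), progress = FALSE)
  validate_lms_reference(ref)
}

validate_lms_reference <- function(ref) {
  check_columns(ref, c("sex", "age_months", "metric", "L", "M", "S"), "LMS")
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    stop("LMS reference requires M > 0 and S > 0", call. = FALSE)
  }
  if (!all(ref$metric %in% LMS_METRICS)) {
    stop("unknown LMS metric; expected one of: ",
         paste(LMS_METRICS, collapse = ", "), call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(ref)), paste(ref$sex, ref$metric))
  for (idx in split_idx) {
    if (is.unsorted(ref$age_months[idx], strictly = TRUE)) {
      stop("age_months must be strictly increasing within sex/metric",
           call. = FALSE)
    }
  }
  as_tibble(ref)
}

#' Synthetic LMS reference table
#'
#' A smooth, synthetic growth reference (ages 24-228 months, both sexes,
#' height-for-age and BMI-for-age) shipped with the package so that examples
#' and tests need no external download. It is *not* a published growth
#' standard; substitute a real table (same schema) for substantive use.
#'
#' @return the reference tibble.
#' @export
lms_reference_synthetic <- function() {
  path <- system.file("extdata", "lms_reference_synthetic.csv",
                      package = "earlytnf")
  if (!nzchar(path)) {  # during development, before installation
    path <- file.path("inst", "extdata", "lms_reference_synthetic.csv")
  }
  read_lms_reference(path)
}

## interpolate (L, M, S) linearly in age for one sex/metric block
lms_lookup <- function(ref, sex, metric, age_months) {
  out <- matrix(NA_real_, length(age_months), 3L,
                dimnames = list(NULL, c("L", "M", "S")))
  for (s in unique(sex[!is.na(sex)])) {
    block <- ref[ref$sex == s & ref$metric == metric, ]
    if (!nrow(block)) next
    sel <- which(!is.na(sex) & sex == s & !is.na(age_months))
    inside <- sel[age_months[sel] >= min(block$age_months) &
                    age_months[sel] <= max(block$age_months)]
    outside <- setdiff(sel, inside)
    if (length(outside)) {
      warning(sprintf("%d visit(s) outside the %s LMS age range; Z-scores set missing",
                      length(outside), metric), call. = FALSE)
    }
    for (par in c("L", "M", "S")) {
      out[inside, par] <- stats::approx(block$age_months, block[[par]],
                                        xout = age_months[inside])$y
    }
  }
  out
}

#' Growth Z-scores for every visit in a cohort
#'
#' Computes height-for-age and BMI-for-age Z-scores for each visit with the
#' required anthropometrics, interpolating the reference (L, M, S) linearly
#' in age between bracketing rows. Age at a visit is the baseline age plus
#' days since diagnosis. BMI is computed as `weight_kg / (height_cm/100)^2`.
#' Visits outside the reference age range get missing Z-scores with a
#' warning, as do visits missing the measurement; |z| > 6 triggers an
#' implausibility warning.
#'
#' @param cohort a [cd_cohort] object.
#' @param ref_table an LMS reference (see [read_lms_reference()]).
#' @return tibble: `id`, `nominal_month`, `day`, `age_months`, `hfa_z`,
#'   `bmi_z`.
#' @export
visit_zscores <- function(cohort, ref_table = lms_reference_synthetic()) {
  stopifnot(inherits(cohort, "cd_cohort"))
  validate_lms_reference(ref_table)
  v <- cohort$visits
  b <- cohort$baseline
  m <- match(v$id, b$id)
  age_months <- b$age_years[m] * 12 + v$day / 30.4375
  sex <- b$sex[m]

  hfa <- lms_lookup(ref_table, sex, "height_for_age", age_months)
  hfa_z <- rep(NA_real_, nrow(v))
  ok <- !is.na(v$height_cm) & !is.na(hfa[, "M"])
  hfa_z[ok] <- lms_zscore(v$height_cm[ok], hfa[ok, "L"], hfa[ok, "M"],
                          hfa[ok, "S"])

  bmiref <- lms_lookup(ref_table, sex, "bmi_for_age", age_months)
  bmi <- v$weight_kg / (v$height_cm / 100)^2
  bmi_z <- rep(NA_real_, nrow(v))
  ok <- !is.na(bmi) & !is.na(bmiref[, "M"])
  bmi_z[ok] <- lms_zscore(bmi[ok], bmiref[ok, "L"], bmiref[ok, "M"],
                          bmiref[ok, "S"])

  if (any(abs(c(hfa_z, bmi_z)) > 6, na.rm = TRUE)) {
    warning("Z-score(s) with |z| > 6; check anthropometrics or reference table",
            call. = FALSE)
  }
  tibble(id = v$id, nominal_month = v$nominal_month, day = v$day,
         age_months = age_months, hfa_z = hfa_z, bmi_z = bmi_z)
}

#' Paired change scores between baseline and a horizon visit
#'
#' Computes per-patient deltas (horizon minus baseline) of any per-visit
#' quantity (growth Z-scores, questionnaire totals such as the IMPACT-III
#' total or the EQ-5D VAS), the within-group paired t-test against zero
#' change, and a two-sample comparison of deltas between exposure groups.
#'
#' @param values tibble with columns `id`, `nominal_month`, and the value
#'   column named by `value`; e.g. the output of [visit_zscores()] or
#'   `cohort$visits`.
#' @param value name of the value column.
#' @param groups optional tibble `id`, `group` (e.g. exposure labels) for the
#'   per-group summaries and the between-group test.
#' @param horizon_month horizon nominal month (default 12).
#' @param baseline_month baseline nominal month (default 0).
#' @return a list with `overall` and (when groups are given) `by_group`
#'   tibbles of `n_pairs`, `mean_delta`, `sd_delta`, `p_value_paired`, plus
#'   `group_comparison` (two-sample t-test on deltas, `NA` when either group
#'   has fewer than two pairs).
#' @export
delta_scores <- function(values, value, groups = NULL, horizon_month = 12,
                         baseline_month = 0) {
  stopifnot(value %in% names(values))
  v0 <- values[values$nominal_month == baseline_month, c("id", value)]
  v1 <- values[values$nominal_month == horizon_month, c("id", value)]
  merged <- merge(v0, v1, by = "id", suffixes = c("_0", "_1"))
  delta <- merged[[paste0(value, "_1")]] - merged[[paste0(value, "_0")]]
  keep <- !is.na(delta)
  merged <- merged[keep, , drop = FALSE]
  delta <- delta[keep]

  summarise_delta <- function(d) {
    n <- length(d)
    if (n < 2L) {
      return(tibble(n_pairs = n, mean_delta = if (n) mean(d) else NA_real_,
                    sd_delta = NA_real_, p_value_paired = NA_real_))
    }
    p <- if (sd(d) == 0) {
      if (mean(d) == 0) 1 else 0
    } else {
      stats::t.test(d)$p.value
    }
    tibble(n_pairs = n, mean_delta = mean(d), sd_delta = sd(d),
           p_value_paired = p)
  }

  out <- list(overall = summarise_delta(delta))
  if (!is.null(groups)) {
    g <- groups$group[match(merged$id, groups$id)]
    by_group <- do.call(rbind, lapply(unique(g[!is.na(g)]), function(gr) {
      cbind(tibble(group = gr), summarise_delta(delta[g %in% gr]))
    }))
    out$by_group <- as_tibble(by_group)
    lv <- unique(g[!is.na(g)])
    out$group_comparison <- if (length(lv) == 2L &&
                                all(table(g[!is.na(g)]) >= 2L)) {
      stats::t.test(delta[g %in% lv[1]], delta[g %in% lv[2]])$p.value
    } else {
      NA_real_
    }
  }
  out
}
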
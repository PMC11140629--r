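DEFAULT_SCHEDULE <- c(0, 3, 6, 12, 18, 24)

#' Steroid-free status over a time window
#'
#' A patient is steroid-free over `(from_day, to_day]` when no corticosteroid
#' course overlaps that half-open interval: a course ending exactly at
#' `from_day` does not violate steroid-freedom (so induction steroids
#' finishing before the window are allowed), while a course starting exactly
#' at `to_day` does. Ongoing courses (missing stop day) extend indefinitely.
#'
#' @param cohort a [cd_cohort] object.
#' @param from_day window start (exclusive), days since diagnosis.
#' @param to_day window end (inclusive); scalar, or one value per patient in
#'   baseline order (NA makes that patient's status NA).
#' @return tibble `id`, `steroid_free` (logical).
#' @export
steroid_free <- function(cohort, from_day, to_day) {
  stopifnot(inherits(cohort, "cd_cohort"))
  ids <- cohort$baseline$id
  from_day <- rep_len(from_day, length(ids))
  to_day <- rep_len(to_day, length(ids))
  if (any(from_day > to_day, na.rm = TRUE)) {
    stop("'from_day' must be <= 'to_day'", call. = FALSE)
  }
  th <- cohort$therapies
  st <- th[th$agent == "corticosteroid", , drop = FALSE]
  out <- rep(TRUE, length(ids))
  if (nrow(st)) {
    m <- match(st$id, ids)
    stop_eff <- ifelse(is.na(st$stop_day), Inf, st$stop_day)
    overlap <- st$start_day <= to_day[m] & stop_eff > from_day[m]
    viol <- tapply(overlap, factor(st$id, levels = ids), any)
    out <- as.vector(!(ids %in% st$id & !is.na(viol[ids]) & viol[ids]))
  }
  out[is.na(to_day)] <- NA
  tibble(id = ids, steroid_free = out)
}

## steroid course active on a given day (for point-in-time steroid-freedom)
steroid_active_on <- function(cohort, day) {
  ids <- cohort$baseline$id
  day <- rep_len(day, length(ids))
  st <- cohort$therapies[cohort$therapies$agent == "corticosteroid", ,
                         drop = FALSE]
  active <- rep(FALSE, length(ids))
  if (nrow(st)) {
    m <- match(st$id, ids)
    stop_eff <- ifelse(is.na(st$stop_day), Inf, st$stop_day)
    hit <- st$start_day <= day[m] & stop_eff >= day[m]
    agg <- tapply(hit, factor(st$id, levels = ids), any)
    active <- as.vector(!is.na(agg[ids]) & agg[ids])
  }
  active[is.na(day)] <- NA
  active
}

#' Detect treatment-intensification events
#'
#' Treatment intensification is arm-specific: for early anti-TNF patients it
#' is escalation to a second-line biologic (ustekinumab or vedolizumab); for
#' patients without early anti-TNF it is escalation to *any* biologic agent
#' after the early window (day 90); for either arm, need for IBD-related
#' luminal surgery. In-class anti-TNF switches (infliximab to adalimumab or
#' vice versa) and dose intensification are not treatment escalation. An
#' event on the horizon day itself counts. Biologic courses starting within
#' the early window in a patient classified as *not* early are impossible by
#' construction of the arms and raise a data-consistency error.
#'
#' @param cohort a [cd_cohort] object.
#' @param exposure exposure labels from [classify_exposure()].
#' @param horizon_day last day (inclusive) considered; scalar or per patient.
#' @param thresholds an [analysis_thresholds()] object.
#' @return tibble `id`, `day`, `kind` of the *first* qualifying event per
#'   patient (`day`/`kind` NA when none).
#' @export
detect_intensification <- function(cohort, exposure,
                                   horizon_day,
                                   thresholds = analysis_thresholds()) {
  stopifnot(inherits(cohort, "cd_cohort"))
  ids <- cohort$baseline$id
  horizon_day <- rep_len(horizon_day, length(ids))
  early <- exposure$early_antitnf[match(ids, exposure$id)]
  th <- cohort$therapies

  bio <- th[th$agent %in% BIOLOGIC_AGENTS, , drop = FALSE]
  if (nrow(bio)) {
    m <- match(bio$id, ids)
    bad <- !early[m] & bio$start_day <= thresholds$early_window_days
    if (any(bad, na.rm = TRUE)) {
      stop("data-consistency error: biologic course starting within the early ",
           "window for patient(s) not classified as early anti-TNF: ",
           paste(unique(bio$id[which(bad)]), collapse = ", "), call. = FALSE)
    }
  }

  cand <- tibble(id = character(0), day = numeric(0), kind = character(0))
  if (nrow(bio)) {
    m <- match(bio$id, ids)
    qualifies <- ifelse(early[m],
                        bio$agent %in% SECOND_LINE_AGENTS,
                        bio$start_day > thresholds$early_window_days)
    kind <- ifelse(early[m], "second_line_biologic", "any_biologic_escalation")
    sel <- qualifies & bio$start_day <= horizon_day[m]
    sel[is.na(sel)] <- FALSE  # unknown horizon: no event reported; flags go NA upstream
    cand <- rbind(cand, tibble(id = bio$id[sel], day = bio$start_day[sel],
                               kind = kind[sel]))
  }
  ev <- cohort$events
  surg <- if (nrow(ev)) ev[ev$kind == "luminal_resection", , drop = FALSE] else ev
  if (nrow(surg)) {
    m <- match(surg$id, ids)
    sel <- surg$day <= horizon_day[m]
    sel[is.na(sel)] <- FALSE
    cand <- rbind(cand, tibble(id = surg$id[sel], day = surg$day[sel],
                               kind = rep("luminal_surgery", sum(sel))))
  }
  out <- tibble(id = ids, day = NA_real_, kind = NA_character_)
  if (nrow(cand)) {
    cand <- cand[order(cand$id, cand$day), ]
    firsts <- cand[!duplicated(cand$id), ]
    m <- match(out$id, firsts$id)
    out$day <- firsts$day[m]
    out$kind <- firsts$kind[m]
  }
  out
}

#' Sustained status over scheduled visits
#'
#' Evaluates a per-visit predicate at every *scheduled* visit whose nominal
#' month lies in `[from_month, to_month]` and combines the results
#' tri-state: `TRUE` only when the predicate holds at every scheduled visit
#' in the window; `FALSE` as soon as it definitively fails once (even with
#' other visits missing); otherwise not evaluable (`NA`). A scheduled visit
#' that is absent from the record, or present with an unevaluable predicate,
#' counts as missing. Under `missing_policy = "available"` missing visits
#' are skipped instead, and the status is `TRUE` when the predicate holds at
#' every *observed* scheduled visit (at least one required).
#'
#' @param cohort a [cd_cohort] object.
#' @param predicate function taking the visits tibble and returning one
#'   logical (possibly NA) per row, e.g.
#'   `function(v) categorize_activity(v$wpcdai, v$pga) == "remission"`.
#' @param from_month,to_month nominal-month window (inclusive).
#' @param schedule the protocol visit months.
#' @param missing_policy `"strict"` (default) or `"available"`.
#' @return tibble `id`, `status` (tri-state logical).
#' @export
sustained_status <- function(cohort, predicate, from_month, to_month,
                             schedule = DEFAULT_SCHEDULE,
                             missing_policy = c("strict", "available")) {
  stopifnot(inherits(cohort, "cd_cohort"), from_month <= to_month)
  missing_policy <- match.arg(missing_policy)
  months <- schedule[schedule >= from_month & schedule <= to_month]
  ids <- cohort$baseline$id
  if (!length(months)) {
    return(tibble(id = ids, status = NA))
  }
  v <- cohort$visits
  ok <- predicate(v)
  key <- paste(v$id, v$nominal_month, sep = "\r")
  grid_key <- outer(ids, months, paste, sep = "\r")
  status_mat <- matrix(ok[match(grid_key, key)], nrow = length(ids))
  status <- apply(status_mat, 1L, function(r) {
    if (missing_policy == "available") r <- r[!is.na(r)]
    tri_all(r)
  })
  tibble(id = ids, status = as.logical(status))
}

#' Three-month response to induction therapy
#'
#' Clinical response compares the month-3 visit with baseline: a wPCDAI
#' decrease of more than 37.5 points is a moderate response and more than
#' 17.5 points a small response (strict inequalities). When the wPCDAI is
#' missing at either end, PGA category shifts substitute: an improvement of
#' at least two categories is moderate, at least one category small.
#' FCP response is a follow-up faecal calprotectin at or below half the
#' baseline value (inclusive), or below 250 ug/g outright.
#'
#' @param cohort a [cd_cohort] object.
#' @param thresholds an [analysis_thresholds()] object.
#' @return tibble `id`, `response3m`
#'   (`"none"`/`"small"`/`"moderate"`/NA) and `fcp_responder3m` (tri-state).
#' @export
three_month_response <- function(cohort, thresholds = analysis_thresholds()) {
  stopifnot(inherits(cohort, "cd_cohort"))
  b <- cohort$baseline
  v3 <- cohort$visits[cohort$visits$nominal_month == 3, , drop = FALSE]
  m <- match(b$id, v3$id)
  w0 <- b$wpcdai
  w3 <- v3$wpcdai[m]
  drop <- w0 - w3

  cat_rank <- function(cat) match(cat, ACTIVITY_LEVELS)
  p0 <- cat_rank(categorize_activity(rep(NA_real_, nrow(b)), b$pga,
                                     thresholds$wpcdai_cuts))
  p3 <- cat_rank(categorize_activity(rep(NA_real_, nrow(b)), v3$pga[m],
                                     thresholds$wpcdai_cuts))
  pga_shift <- p0 - p3

  resp <- rep(NA_character_, nrow(b))
  have_w <- !is.na(drop)
  resp[have_w & drop > thresholds$moderate_response_drop] <- "moderate"
  resp[have_w & drop <= thresholds$moderate_response_drop &
         drop > thresholds$small_response_drop] <- "small"
  resp[have_w & drop <= thresholds$small_response_drop] <- "none"
  use_pga <- !have_w & !is.na(pga_shift)
  resp[use_pga & pga_shift >= 2] <- "moderate"
  resp[use_pga & pga_shift == 1] <- "small"
  resp[use_pga & pga_shift <= 0] <- "none"

  f0 <- b$fcp
  f3 <- v3$fcp[m]
  fcp <- rep(NA, nrow(b))
  fcp[!is.na(f3) & f3 < thresholds$nfr_fcp_max] <- TRUE
  both <- !is.na(f3) & f3 >= thresholds$nfr_fcp_max & !is.na(f0)
  fcp[both] <- f3[both] <= (1 - thresholds$fcp_response_fraction) * f0[both]

  tibble(id = b$id, response3m = resp, fcp_responder3m = fcp)
}

#' Derive all outcome flags at a horizon
#'
#' Composes the elementary rules into the full set of tri-state outcome
#' flags for each patient at a horizon (nominal month 12 or 24):
#'
#' * `remission` / `mild_inactive`: point-in-time clinical activity at the
#'   horizon visit;
#' * `ncr`, `nfr`: remission with horizon CRP < 0.5 mg/dl / FCP < 250 ug/g
#'   (strict);
#' * `sfr`, `sfmi`: the point-in-time status with no corticosteroid course
#'   active on the horizon day;
#' * `ssfr`, `ssfmi`: the status sustained at every scheduled visit from
#'   month 3 to the horizon, steroid-free over `(day 90, horizon day]`;
#' * `ssfr_star`, `ssfmi_star`: additionally no treatment-intensification
#'   event up to and including the horizon day;
#' * `ssfr_star_from6`, `ssfmi_star_from6`: the starred outcomes with the
#'   sustained window starting at month 6 (steroid window from the month-6
#'   visit day, or day 183 when that visit is absent);
#' * `mini_category`: MINI-index banding at the horizon visit;
#' * `response3m`, `fcp_responder3m`: three-month response (horizon-free).
#'
#' Missingness propagates as `NA` ("not evaluable") rather than erroring;
#' under the default strict policy a missing scheduled visit makes sustained
#' outcomes not evaluable.
#'
#' @param cohort a [cd_cohort] object.
#' @param horizon_month 12 or 24 (other scheduled months allowed).
#' @param exposure optional exposure labels (computed when `NULL`).
#' @param thresholds an [analysis_thresholds()] object.
#' @param schedule protocol visit months.
#' @param missing_policy passed to [sustained_status()].
#' @return tibble with one row per patient, the flags above plus
#'   `early_antitnf` and `horizon_month`.
#' @export
derive_outcomes <- function(cohort, horizon_month = 12, exposure = NULL,
                            thresholds = analysis_thresholds(),
                            schedule = DEFAULT_SCHEDULE,
                            missing_policy = c("strict", "available")) {
  stopifnot(inherits(cohort, "cd_cohort"))
  missing_policy <- match.arg(missing_policy)
  if (is.null(exposure)) exposure <- classify_exposure(cohort, thresholds)
  b <- cohort$baseline
  ids <- b$id
  v <- cohort$visits
  cuts <- thresholds$wpcdai_cuts

  hv <- v[v$nominal_month == horizon_month, , drop = FALSE]
  m <- match(ids, hv$id)
  day_h <- hv$day[m]
  cat_h <- categorize_activity(hv$wpcdai[m], hv$pga[m], cuts)
  remission <- ifelse(is.na(cat_h), NA, cat_h == "remission")
  mild_inactive <- ifelse(is.na(cat_h), NA, cat_h %in% c("remission", "mild"))

  crp_h <- hv$crp[m]
  fcp_h <- hv$fcp[m]
  ncr <- tri_and(remission, ifelse(is.na(crp_h), NA,
                                   crp_h < thresholds$ncr_crp_max))
  nfr <- tri_and(remission, ifelse(is.na(fcp_h), NA,
                                   fcp_h < thresholds$nfr_fcp_max))

  no_steroid_now <- !steroid_active_on(cohort, day_h)
  sfr <- tri_and(remission, no_steroid_now)
  sfmi <- tri_and(mild_inactive, no_steroid_now)

  rem_pred <- function(vv) {
    cc <- categorize_activity(vv$wpcdai, vv$pga, cuts)
    ifelse(is.na(cc), NA, cc == "remission")
  }
  mi_pred <- function(vv) {
    cc <- categorize_activity(vv$wpcdai, vv$pga, cuts)
    ifelse(is.na(cc), NA, cc %in% c("remission", "mild"))
  }
  sus_rem <- sustained_status(cohort, rem_pred, 3, horizon_month, schedule,
                              missing_policy)$status
  sus_mi <- sustained_status(cohort, mi_pred, 3, horizon_month, schedule,
                             missing_policy)$status

  sf_window <- steroid_free(cohort, thresholds$steroid_free_from_day,
                            day_h)$steroid_free
  ssfr <- tri_and(sus_rem, sf_window)
  ssfmi <- tri_and(sus_mi, sf_window)

  intens <- detect_intensification(cohort, exposure, day_h, thresholds)
  ## intensification is known FALSE only when the horizon day is known
  no_intens <- ifelse(is.na(day_h) & is.na(intens$day), NA, is.na(intens$day))
  ssfr_star <- tri_and(ssfr, no_intens)
  ssfmi_star <- tri_and(ssfmi, no_intens)

  v6 <- v[v$nominal_month == 6, , drop = FALSE]
  day_6 <- v6$day[match(ids, v6$id)]
  day_6[is.na(day_6)] <- 183
  sus_rem6 <- sustained_status(cohort, rem_pred, 6, horizon_month, schedule,
                               missing_policy)$status
  sus_mi6 <- sustained_status(cohort, mi_pred, 6, horizon_month, schedule,
                              missing_policy)$status
  sf6 <- steroid_free(cohort, day_6, day_h)$steroid_free
  ssfr_star_from6 <- tri_and(tri_and(sus_rem6, sf6), no_intens)
  ssfmi_star_from6 <- tri_and(tri_and(sus_mi6, sf6), no_intens)

  mini_category <- categorize_mini(hv$mini_index[m], thresholds, warn = FALSE)
  resp <- three_month_response(cohort, thresholds)

  tibble(id = ids,
         horizon_month = horizon_month,
         early_antitnf = exposure$early_antitnf[match(ids, exposure$id)],
         remission = remission, mild_inactive = mild_inactive,
         ncr = ncr, nfr = nfr,
         sfr = sfr, sfmi = sfmi,
         ssfr = ssfr, ssfr_star = ssfr_star,
         ssfmi = ssfmi, ssfmi_star = ssfmi_star,
         ssfr_star_from6 = ssfr_star_from6,
         ssfmi_star_from6 = ssfmi_star_from6,
         mini_category = mini_category,
         mh_mini = ifelse(is.na(mini_category), NA, mini_category == "MH"),
         response3m = resp$response3m[match(ids, resp$id)],
         fcp_responder3m = resp$fcp_responder3m[match(ids, resp$id)])
}

#' Point-in-time steroid-free status at month 3
#'
#' Convenience accessor for the conditional ("time-independent effect")
#' analyses: steroid-free remission (SFR) and steroid-free mild-or-inactive
#' disease (SFMI) at the month-3 visit.
#'
#' @inheritParams derive_outcomes
#' @return tibble `id`, `sfr3m`, `sfmi3m` (tri-state).
#' @export
status_at_3m <- function(cohort, thresholds = analysis_thresholds()) {
  v3 <- cohort$visits[cohort$visits$nominal_month == 3, , drop = FALSE]
  ids <- cohort$baseline$id
  m <- match(ids, v3$id)
  cat3 <- categorize_activity(v3$wpcdai[m], v3$pga[m], thresholds$wpcdai_cuts)
  no_ster <- !steroid_active_on(cohort, v3$day[m])
  tibble(id = ids,
         sfr3m = tri_and(ifelse(is.na(cat3), NA, cat3 == "remission"), no_ster),
         sfmi3m = tri_and(ifelse(is.na(cat3), NA,
                                 cat3 %in% c("remission", "mild")), no_ster))
}

#' Condition a set of outcome flags on 3-month status
#'
#' Returns the patients whose month-3 condition (e.g. SFR or SFMI) is
#' definitively `TRUE`, for downstream comparison of sustained-outcome rates
#' among early responders ("time-independent" effect of early therapy).
#'
#' @param flags a tibble with an `id` column (e.g. from [derive_outcomes()]).
#' @param condition logical vector aligned with `flags` rows (tri-state);
#'   typically a column of [status_at_3m()].
#' @return the subset of `flags` rows with `condition` identically `TRUE`.
#' @export
conditional_subset <- function(flags, condition) {
  stopifnot(nrow(flags) == length(condition))
  flags[which(condition), , drop = FALSE]
}
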
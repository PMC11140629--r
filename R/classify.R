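ACTIVITY_LEVELS <- c("remission", "mild", "moderate", "severe")
SESCD_LEVELS <- c("MH", "mild", "moderate-severe")
ANTITNF_AGENTS <- c("infliximab", "adalimumab")
SECOND_LINE_AGENTS <- c("ustekinumab", "vedolizumab")
BIOLOGIC_AGENTS <- c(ANTITNF_AGENTS, SECOND_LINE_AGENTS)
INDUCTION_AGENTS <- c("een", "corticosteroid", "5asa")

#' Categorise clinical disease activity
#'
#' Maps wPCDAI scores (0-127.5) to the four-level activity scale
#' remission / mild / moderate / severe. The physician's global assessment
#' (PGA), already recorded on the same four levels, is used as a fallback
#' only where the wPCDAI is missing. When both are missing the category is
#' missing (`NA`), not an error.
#'
#' @param wpcdai numeric vector of wPCDAI scores (may contain NAs).
#' @param pga character vector of PGA categories on the same levels
#'   (`"inactive"` is accepted as a synonym of `"remission"`), or `NULL`.
#' @param cuts three ascending wPCDAI cut points; scores below `cuts[1]` are
#'   remission, in `[cuts[1], cuts[2]]` mild, in `(cuts[2], cuts[3]]`
#'   moderate, above `cuts[3]` severe.
#' @return character vector on the levels
#'   `c("remission", "mild", "moderate", "severe")` with NAs preserved.
#' @examples
#' categorize_activity(c(0, 12.5, 51, 60, NA), pga = c(NA, NA, NA, NA, "severe"))
#' @export
categorize_activity <- function(wpcdai, pga = NULL,
                                cuts = analysis_thresholds()$wpcdai_cuts) {
  stopifnot(length(cuts) == 3L, !is.unsorted(cuts, strictly = TRUE))
  n <- max(length(wpcdai), length(pga), 1L)
  w <- rep_len(if (length(wpcdai)) wpcdai else NA_real_, n)
  if (any(w < 0 | w > 127.5, na.rm = TRUE)) {
    stop("wPCDAI must lie in [0, 127.5]", call. = FALSE)
  }
  out <- rep(NA_character_, n)
  out[!is.na(w) & w < cuts[1]] <- "remission"
  out[!is.na(w) & w >= cuts[1] & w <= cuts[2]] <- "mild"
  out[!is.na(w) & w > cuts[2] & w <= cuts[3]] <- "moderate"
  out[!is.na(w) & w > cuts[3]] <- "severe"
  if (!is.null(pga)) {
    p <- rep_len(as.character(pga), n)
    p[p %in% "inactive"] <- "remission"
    bad <- !is.na(p) & !p %in% ACTIVITY_LEVELS
    if (any(bad)) {
      stop("unknown PGA category: ", paste(unique(p[bad]), collapse = ", "),
           call. = FALSE)
    }
    use <- is.na(out) & !is.na(p)
    out[use] <- p[use]
  }
  out
}

#' Moderate-to-severe indicator from an activity category
#'
#' @param category character vector of activity categories.
#' @return logical vector, `TRUE` for moderate or severe, NA preserved.
#' @export
is_moderate_severe <- function(category) {
  ifelse(is.na(category), NA, category %in% c("moderate", "severe"))
}

#' Categorise endoscopic severity from the SES-CD total
#'
#' SES-CD below 3 is mucosal healing (MH), 3-9 mild endoscopic activity,
#' and 10 or more moderate-to-severe endoscopic activity.
#'
#' @param sescd_total numeric vector of SES-CD totals (>= 0 or NA).
#' @param thresholds an [analysis_thresholds()] object.
#' @return character vector on levels `c("MH", "mild", "moderate-severe")`.
#' @examples
#' categorize_sescd(c(0, 2, 3, 9, 10, NA))
#' @export
categorize_sescd <- function(sescd_total, thresholds = analysis_thresholds()) {
  if (any(sescd_total < 0, na.rm = TRUE)) {
    stop("SES-CD total must be non-negative", call. = FALSE)
  }
  out <- rep(NA_character_, length(sescd_total))
  ok <- !is.na(sescd_total)
  out[ok & sescd_total < thresholds$sescd_mh_max] <- "MH"
  out[ok & sescd_total >= thresholds$sescd_mh_max &
        sescd_total < thresholds$sescd_modsev_min] <- "mild"
  out[ok & sescd_total >= thresholds$sescd_modsev_min] <- "moderate-severe"
  out
}

#' Categorise the MINI-index as a mucosal-healing proxy
#'
#' A MINI-index strictly below 3 is used as a proxy for endoscopic mucosal
#' healing. The mild vs moderate-severe boundary above that has no published
#' validation; the default (mild up to 8, inclusive) is an unvalidated
#' convenience banding and a warning is issued the first time it is relied
#' upon in a session.
#'
#' @param mini numeric vector of externally computed MINI-index values.
#' @param thresholds an [analysis_thresholds()] object.
#' @param warn warn when the unvalidated mild/moderate-severe boundary is
#'   exercised (once per session).
#' @return character vector on levels `c("MH", "mild", "moderate-severe")`.
#' @export
categorize_mini <- function(mini, thresholds = analysis_thresholds(),
                            warn = TRUE) {
  out <- rep(NA_character_, length(mini))
  ok <- !is.na(mini)
  out[ok & mini < thresholds$mini_mh_max] <- "MH"
  out[ok & mini >= thresholds$mini_mh_max &
        mini <= thresholds$mini_mild_max] <- "mild"
  out[ok & mini > thresholds$mini_mild_max] <- "moderate-severe"
  if (warn && any(out %in% c("mild", "moderate-severe")) &&
      !isTRUE(getOption("earlytnf.mini_band_warned"))) {
    options(earlytnf.mini_band_warned = TRUE)
    warning("the MINI-index mild vs moderate-severe boundary (",
            thresholds$mini_mild_max, ") is an unvalidated default; only the ",
            "mucosal-healing boundary (< ", thresholds$mini_mh_max,
            ") is validated", call. = FALSE)
  }
  out
}

#' Classify early anti-TNF exposure
#'
#' A patient is in the early anti-TNF group when the earliest infliximab or
#' adalimumab course starts within the early window (default 90 days after
#' diagnosis, closed interval). Exposure is additionally flagged "upfront"
#' when that anti-TNF course is the chronologically first induction-class
#' therapy, i.e. no exclusive enteral nutrition, corticosteroid or
#' 5-aminosalicylate course starts strictly before it (immunomodulator
#' co-medication does not void upfront status). Patients without any anti-TNF
#' course are classified as not early, not as an error.
#'
#' @param cohort a [cd_cohort] object.
#' @param thresholds an [analysis_thresholds()] object.
#' @return a tibble with one row per patient: `id`, `early_antitnf`
#'   (logical), `first_antitnf_day`, `first_agent`, `upfront`.
#' @export
classify_exposure <- function(cohort, thresholds = analysis_thresholds()) {
  stopifnot(inherits(cohort, "cd_cohort"))
  th <- cohort$therapies
  ids <- cohort$baseline$id
  tnf <- th[th$agent %in% ANTITNF_AGENTS, , drop = FALSE]
  first <- tibble(id = ids, first_antitnf_day = NA_real_,
                  first_agent = NA_character_)
  if (nrow(tnf)) {
    ord <- order(tnf$id, tnf$start_day)
    tnf <- tnf[ord, , drop = FALSE]
    keep <- !duplicated(tnf$id)
    m <- match(first$id, tnf$id[keep])
    first$first_antitnf_day <- tnf$start_day[keep][m]
    first$first_agent <- tnf$agent[keep][m]
  }
  early <- !is.na(first$first_antitnf_day) &
    first$first_antitnf_day <= thresholds$early_window_days

  ## earliest induction-class (EEN / steroid / 5-ASA) start per patient
  ind <- th[th$agent %in% INDUCTION_AGENTS, , drop = FALSE]
  first_ind <- rep(Inf, length(ids))
  if (nrow(ind)) {
    agg <- tapply(ind$start_day, ind$id, min)
    m <- match(ids, names(agg))
    first_ind[!is.na(m)] <- as.numeric(agg[m[!is.na(m)]])
  }
  upfront <- early & first$first_antitnf_day <= first_ind
  tibble(id = ids,
         early_antitnf = early,
         first_antitnf_day = first$first_antitnf_day,
         first_agent = first$first_agent,
         upfront = upfront)
}

#' Derive predictors of poor outcome (POPOs)
#'
#' Computes the five ESPGHAN predictors of poor outcome as tri-state flags:
#' * `perianal`: perianal disease at diagnosis (missing assumed negative);
#' * `deep_colonic_ulcers`: any colonic SES-CD "size of ulcer" sub-score of
#'   large or very large; missing when no colonic ulcer sub-score is observed
#'   and none of the observed ones qualifies;
#' * `extensive_disease`: ileocolonic disease (L3) together with proximal
#'   upper-GI involvement (L4a and/or L4b), regardless of severity;
#' * `growth_delay`: baseline height-for-age Z-score strictly below -1.5;
#' * `complicated_disease`: B2 and/or B3 behaviour, or B1 inflammatory
#'   disease with narrowing but without prestenotic dilatation (missing
#'   assumed negative).
#'
#' Perianal and complicated disease are deterministically filled to `FALSE`
#' when missing; the remaining flags stay `NA` when unresolvable and are left
#' for multiple imputation. `any_popo` is `TRUE` as soon as one component is
#' `TRUE`, `FALSE` only when all five are `FALSE`, otherwise `NA`.
#'
#' @param cohort a [cd_cohort] object.
#' @param thresholds an [analysis_thresholds()] object.
#' @param hfa_z optional data frame `id`, `hfa_z` with baseline
#'   height-for-age Z-scores; when `NULL` and `ref_table` is supplied they
#'   are computed from baseline anthropometrics via [visit_zscores()].
#' @param ref_table optional LMS reference table (see
#'   [read_lms_reference()]); ignored when `hfa_z` is given.
#' @return tibble: `id`, the five flags, `any_popo` (all logical, tri-state).
#' @export
derive_popos <- function(cohort, thresholds = analysis_thresholds(),
                         hfa_z = NULL, ref_table = NULL) {
  stopifnot(inherits(cohort, "cd_cohort"))
  b <- cohort$baseline

  perianal <- ifelse(is.na(b$perianal), FALSE, b$perianal)

  ulcer_cols <- intersect(COLONIC_ULCER_COLS, names(b))
  deep <- rep(NA, nrow(b))
  if (length(ulcer_cols)) {
    sub <- as.matrix(b[, ulcer_cols])
    ## tri_any over "is this segment deeply ulcerated?", NA where unobserved
    seg_deep <- matrix(ifelse(is.na(sub), NA, sub %in% c("large", "very_large")),
                       nrow = nrow(b))
    deep <- apply(seg_deep, 1L, tri_any)
  }

  extensive <- rep(NA, nrow(b))
  loc_known <- !is.na(b$paris_location)
  extensive[loc_known & b$paris_location != "L3"] <- FALSE
  l3 <- loc_known & b$paris_location == "L3"
  extensive[l3 & !is.na(b$upper_gi)] <-
    b$upper_gi[l3 & !is.na(b$upper_gi)] %in% c("L4a", "L4b", "L4ab")

  if (is.null(hfa_z) && !is.null(ref_table)) {
    z <- visit_zscores(cohort, ref_table)
    z0 <- z[z$nominal_month == 0, c("id", "hfa_z")]
    hfa_z <- z0
  }
  growth <- rep(NA, nrow(b))
  if (!is.null(hfa_z)) {
    m <- match(b$id, hfa_z$id)
    zb <- hfa_z$hfa_z[m]
    growth <- ifelse(is.na(zb), NA, zb < thresholds$growth_delay_z)
  }

  beh <- b$behaviour
  narrow <- ifelse(is.na(b$b1_narrowing_no_dilatation), FALSE,
                   b$b1_narrowing_no_dilatation)
  complicated <- ifelse(is.na(beh), FALSE,
                        beh %in% c("B2", "B3", "B2B3") | (beh == "B1" & narrow))

  flags <- cbind(perianal, deep, extensive, growth, complicated)
  any_popo <- apply(flags, 1L, tri_any)
  tibble(id = b$id,
         perianal = as.logical(perianal),
         deep_colonic_ulcers = as.logical(deep),
         extensive_disease = as.logical(extensive),
         growth_delay = as.logical(growth),
         complicated_disease = as.logical(complicated),
         any_popo = as.logical(any_popo))
}
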
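## column schemas for the four cohort tables (CSV, UTF-8, missing = empty)
COLONIC_ULCER_COLS <- c("ulcer_right_colon", "ulcer_transverse",
                        "ulcer_left_colon", "ulcer_rectum")
ULCER_COLS <- c("ulcer_ileum", COLONIC_ULCER_COLS)
ULCER_LEVELS <- c("none", "aphthous", "large", "very_large")
LOCATION_LEVELS <- c("L1", "L2", "L3", "L4")
UPPER_GI_LEVELS <- c("none", "L4a", "L4b", "L4ab")
BEHAVIOUR_LEVELS <- c("B1", "B2", "B3", "B2B3")
AGENT_LEVELS <- c("infliximab", "adalimumab", "ustekinumab", "vedolizumab",
                  "corticosteroid", "een", "5asa", "immunomodulator",
                  "dietary", "antibiotic", "other")
EVENT_LEVELS <- c("luminal_resection", "other")

BASELINE_COLS <- c("id", "age_years", "sex", "time_to_diagnosis_days",
                   "crp", "esr", "fcp", "wpcdai", "pga", "sescd_total",
                   ULCER_COLS, "paris_location", "upper_gi", "behaviour",
                   "b1_narrowing_no_dilatation", "perianal",
                   "height_cm", "weight_kg", "last_followup_day",
                   "dropout_before_1y")
VISIT_COLS <- c("id", "nominal_month", "day", "wpcdai", "pga", "crp", "fcp",
                "mini_index", "height_cm", "weight_kg",
                "impact3_total", "eq5d_vas")
THERAPY_COLS <- c("id", "agent", "start_day", "stop_day", "dose_intensified")
EVENT_COLS <- c("id", "day", "kind")

#' Construct a Crohn's disease cohort object
#'
#' A cohort is four linked tables sharing the patient `id` key: one baseline
#' row per patient, visit-level assessments at nominal months 0/3/6/12/18/24
#' (and beyond), therapy courses with start/stop days, and surgery events.
#' All times are days since diagnosis (day 0).
#'
#' @param baseline,visits,therapies,events data frames following the
#'   documented column schema (see [read_cohort()]).
#' @param validate run [validate_cohort()] (default `TRUE`).
#' @return an object of class `cd_cohort`.
#' @export
cd_cohort <- function(baseline, visits = NULL, therapies = NULL,
                      events = NULL, validate = TRUE) {
  empty <- function(cols) {
    df <- as_tibble(stats::setNames(rep(list(logical(0)), length(cols)), cols))
    df
  }
  obj <- structure(list(
    baseline = as_tibble(baseline),
    visits = if (is.null(visits)) empty(VISIT_COLS) else as_tibble(visits),
    therapies = if (is.null(therapies)) empty(THERAPY_COLS) else as_tibble(therapies),
    events = if (is.null(events)) empty(EVENT_COLS) else as_tibble(events)
  ), class = "cd_cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' @export
print.cd_cohort <- function(x, ...) {
  cat(sprintf(paste0("<cd_cohort> %d patients, %d visits, %d therapy courses,",
                     " %d events\n"),
              nrow(x$baseline), nrow(x$visits), nrow(x$therapies),
              nrow(x$events)))
  invisible(x)
}

#' Validate a cohort against its invariants
#'
#' Checks the schema (required columns), referential integrity (every visit,
#' therapy and event row must name a known patient id), and the domain
#' invariants: ages in (2, 18], wPCDAI in \[0, 127.5\], non-negative
#' laboratory values, therapy stop on/after start, non-negative event days,
#' strictly increasing visit days and unique nominal months per patient, and
#' follow-up extending at least to the last recorded event.
#'
#' @param cohort a [cd_cohort] object.
#' @return the cohort, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(cohort) {
  b <- check_columns(cohort$baseline, BASELINE_COLS, "baseline")
  v <- cohort$visits
  th <- cohort$therapies
  ev <- cohort$events
  if (nrow(v)) check_columns(v, VISIT_COLS, "visits")
  if (nrow(th)) check_columns(th, THERAPY_COLS, "therapies")
  if (nrow(ev)) check_columns(ev, EVENT_COLS, "events")

  if (anyDuplicated(b$id)) stop("duplicate patient ids in baseline", call. = FALSE)
  for (nm in c("visits", "therapies", "events")) {
    child <- cohort[[nm]]
    if (nrow(child)) {
      orphans <- setdiff(unique(child$id), b$id)
      if (length(orphans)) {
        stop(sprintf("%s table references unknown patient id(s): %s",
                     nm, paste(utils::head(orphans, 5L), collapse = ", ")),
             call. = FALSE)
      }
    }
  }

  if (any(b$age_years <= 2 | b$age_years > 18, na.rm = TRUE)) {
    stop("age_years must lie in (2, 18]", call. = FALSE)
  }
  if (any(b$wpcdai < 0 | b$wpcdai > 127.5, na.rm = TRUE)) {
    stop("baseline wPCDAI must lie in [0, 127.5]", call. = FALSE)
  }
  for (lab in c("crp", "esr", "fcp", "sescd_total")) {
    if (any(b[[lab]] < 0, na.rm = TRUE)) {
      stop(sprintf("baseline %s must be non-negative", lab), call. = FALSE)
    }
  }
  check_levels <- function(x, levels, what) {
    bad <- !is.na(x) & !x %in% levels
    if (any(bad)) {
      stop(sprintf("invalid %s value(s): %s", what,
                   paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
  }
  check_levels(b$sex, c("M", "F"), "sex")
  check_levels(b$paris_location, LOCATION_LEVELS, "paris_location")
  check_levels(b$upper_gi, UPPER_GI_LEVELS, "upper_gi")
  check_levels(b$behaviour, BEHAVIOUR_LEVELS, "behaviour")
  check_levels(b$pga, c(ACTIVITY_LEVELS, "inactive"), "pga")
  for (uc in intersect(ULCER_COLS, names(b))) {
    check_levels(b[[uc]], ULCER_LEVELS, uc)
  }

  if (nrow(v)) {
    if (any(v$day < 0, na.rm = TRUE)) stop("visit day must be >= 0", call. = FALSE)
    check_levels(v$pga, c(ACTIVITY_LEVELS, "inactive"), "visit pga")
    ord <- order(v$id, v$day)
    vs <- v[ord, ]
    same <- duplicated(vs$id)
    if (any(same & diff(c(NA, vs$day)) <= 0, na.rm = TRUE)) {
      stop("visit days must be strictly increasing within patient", call. = FALSE)
    }
    if (anyDuplicated(paste(v$id, v$nominal_month))) {
      stop("nominal_month must be unique within patient", call. = FALSE)
    }
  }
  if (nrow(th)) {
    check_levels(th$agent, AGENT_LEVELS, "agent")
    if (any(th$stop_day < th$start_day, na.rm = TRUE)) {
      stop("therapy stop_day must be >= start_day", call. = FALSE)
    }
    if (any(th$start_day < 0, na.rm = TRUE)) {
      stop("therapy start_day must be >= 0", call. = FALSE)
    }
  }
  if (nrow(ev)) {
    check_levels(ev$kind, EVENT_LEVELS, "event kind")
    if (any(ev$day < 0, na.rm = TRUE)) stop("event day must be >= 0", call. = FALSE)
  }

  last_event <- rep(0, nrow(b))
  for (nm in c("visits", "events")) {
    child <- cohort[[nm]]
    if (nrow(child)) {
      agg <- tapply(child$day, child$id, max, na.rm = TRUE)
      m <- match(b$id, names(agg))
      last_event <- pmax(last_event, ifelse(is.na(m), 0, as.numeric(agg[m])),
                         na.rm = TRUE)
    }
  }
  if (any(b$last_followup_day < last_event, na.rm = TRUE)) {
    stop("last_followup_day must be >= the last recorded visit/event day",
         call. = FALSE)
  }
  invisible(cohort)
}

#' Restrict a cohort to the analysis set
#'
#' Drops patients flagged as having dropped out before one year of follow-up
#' (the minimum follow-up the analysis requires).
#'
#' @param cohort a [cd_cohort] object.
#' @return a [cd_cohort] with those patients removed from all four tables.
#' @export
analysis_set <- function(cohort) {
  keep <- cohort$baseline$id[!cohort$baseline$dropout_before_1y %in% TRUE]
  sub <- lapply(cohort[c("baseline", "visits", "therapies", "events")],
                function(df) df[df$id %in% keep, , drop = FALSE])
  structure(sub, class = "cd_cohort")
}

cohort_col_types <- function() {
  chr <- readr::col_character()
  dbl <- readr::col_double()
  lgl <- readr::col_logical()
  list(
    baseline = do.call(readr::cols, stats::setNames(list(
      chr, dbl, chr, dbl, dbl, dbl, dbl, dbl, chr, dbl,
      chr, chr, chr, chr, chr, chr, chr, chr, lgl, lgl,
      dbl, dbl, dbl, lgl),
      BASELINE_COLS)),
    visits = do.call(readr::cols, stats::setNames(
      list(chr, dbl, dbl, dbl, chr, dbl, dbl, dbl, dbl, dbl, dbl, dbl),
      VISIT_COLS)),
    therapies = do.call(readr::cols, stats::setNames(
      list(chr, chr, dbl, dbl, lgl), THERAPY_COLS)),
    events = do.call(readr::cols, stats::setNames(list(chr, dbl, chr),
                                                  EVENT_COLS))
  )
}

#' Read a cohort from its four CSV tables
#'
#' Reads and links the baseline, visit, therapy and event tables
#' (comma-separated, UTF-8, empty field = missing, enumerations as lowercase
#' strings except `sex` and Paris codes) and validates the result. Round-trips
#' with [write_cohort()].
#'
#' @param baseline_path,visits_path,therapy_path,events_path file paths.
#' @return a validated [cd_cohort].
#' @export
read_cohort <- function(baseline_path, visits_path, therapy_path, events_path) {
  ct <- cohort_col_types()
  rd <- function(path, types) {
    readr::read_csv(path, col_types = types, na = "", progress = FALSE)
  }
  cd_cohort(baseline = rd(baseline_path, ct$baseline),
            visits = rd(visits_path, ct$visits),
            therapies = rd(therapy_path, ct$therapies),
            events = rd(events_path, ct$events))
}

#' Write a cohort to four CSV tables
#'
#' Emits the exact schema [read_cohort()] reads, so a write/read cycle
#' reproduces the cohort.
#'
#' @param cohort a [cd_cohort] object.
#' @param dir output directory (created if needed).
#' @return the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("baseline.csv", "visits.csv", "therapies.csv",
                            "events.csv"))
  cols <- list(BASELINE_COLS, VISIT_COLS, THERAPY_COLS, EVENT_COLS)
  tabs <- cohort[c("baseline", "visits", "therapies", "events")]
  for (i in seq_along(tabs)) {
    df <- tabs[[i]]
    if (!nrow(df)) {
      df <- as_tibble(stats::setNames(rep(list(logical(0)), length(cols[[i]])),
                                      cols[[i]]))
    }
    readr::write_csv(df[, cols[[i]]], paths[i], na = "")
  }
  invisible(paths)
}
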
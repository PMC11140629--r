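## Hand-built cohort fixtures -------------------------------------------------

## one baseline row with sensible defaults, overridable per field
base_row <- function(id, ...) {
  row <- tibble::tibble(
    id = id, age_years = 13, sex = "M", time_to_diagnosis_days = 120,
    crp = 2.5, esr = 30, fcp = 800, wpcdai = 45, pga = "moderate",
    sescd_total = 12,
    ulcer_ileum = "aphthous", ulcer_right_colon = "none",
    ulcer_transverse = "none", ulcer_left_colon = "none",
    ulcer_rectum = "none",
    paris_location = "L3", upper_gi = "none", behaviour = "B1",
    b1_narrowing_no_dilatation = FALSE, perianal = FALSE,
    height_cm = 150, weight_kg = 40,
    last_followup_day = 800, dropout_before_1y = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

visit_row <- function(id, month, day = round(30.4375 * month), ...) {
  row <- tibble::tibble(
    id = id, nominal_month = month, day = day,
    wpcdai = NA_real_, pga = NA_character_, crp = NA_real_, fcp = NA_real_,
    mini_index = NA_real_, height_cm = NA_real_, weight_kg = NA_real_,
    impact3_total = NA_real_, eq5d_vas = NA_real_)
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

therapy_row <- function(id, agent, start_day, stop_day = NA_real_,
                        dose_intensified = FALSE) {
  tibble::tibble(id = id, agent = agent, start_day = start_day,
                 stop_day = stop_day, dose_intensified = dose_intensified)
}

event_row <- function(id, day, kind = "luminal_resection") {
  tibble::tibble(id = id, day = day, kind = kind)
}

## a patient in sustained remission at months 3/6/12, no steroids after
## induction, early infliximab at day 28
remission_patient <- function(id = "A", tnf_day = 28) {
  list(
    baseline = base_row(id),
    visits = dplyr::bind_rows(
      visit_row(id, 0, 0, wpcdai = 45, pga = "moderate", crp = 2.5, fcp = 800),
      visit_row(id, 3, 91, wpcdai = 5, pga = "remission", crp = 0.3, fcp = 120),
      visit_row(id, 6, 183, wpcdai = 8, pga = "remission", crp = 0.2, fcp = 100),
      visit_row(id, 12, 365, wpcdai = 3, pga = "remission", crp = 0.3,
                fcp = 90)),
    therapies = therapy_row(id, "infliximab", tnf_day),
    events = NULL)
}

## assemble a cd_cohort from a list of per-patient pieces
assemble_cohort <- function(...) {
  pieces <- list(...)
  nz <- function(part) {
    df <- dplyr::bind_rows(lapply(pieces, `[[`, part))
    if (nrow(df)) df else NULL
  }
  cd_cohort(baseline = nz("baseline"), visits = nz("visits"),
            therapies = nz("therapies"), events = nz("events"))
}

## a sim_config with all missingness switched off
config_no_missingness <- function(...) {
  cfg <- sim_config(...)
  cfg$missingness$baseline[] <- 0
  cfg$missingness$visits[] <- 0
  cfg$missingness$endoscopy_block <- 0
  cfg
}

## delete a fraction of one column completely at random
mcar_delete <- function(data, column, rate, seed) {
  withr::with_seed(seed, {
    miss <- runif(nrow(data)) < rate
    data[[column]][miss] <- NA
    data
  })
}
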
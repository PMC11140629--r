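test_that("steroid-freedom uses a half-open window", {
  coh <- assemble_cohort(
    list(baseline = base_row("A"),
         therapies = therapy_row("A", "corticosteroid", 0, 80)),
    list(baseline = base_row("B"),
         therapies = therapy_row("B", "corticosteroid", 0, 120)),
    list(baseline = base_row("C")),
    list(baseline = base_row("D"),   # ends exactly at the window start
         therapies = therapy_row("D", "corticosteroid", 30, 91)),
    list(baseline = base_row("E"),   # ongoing course (no stop day)
         therapies = therapy_row("E", "corticosteroid", 200)))
  sf <- steroid_free(coh, 91, 365)
  expect_equal(sf$steroid_free, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_error(steroid_free(coh, 100, 50), "from_day")
})

test_that("intensification is arm-specific and ignores in-class switches", {
  coh <- assemble_cohort(
    ## early arm escalating to vedolizumab
    list(baseline = base_row("A"),
         therapies = dplyr::bind_rows(therapy_row("A", "infliximab", 20),
                                      therapy_row("A", "vedolizumab", 200))),
    ## no-early arm escalating to infliximab after day 90
    list(baseline = base_row("B"),
         therapies = therapy_row("B", "infliximab", 150)),
    ## early arm with an in-class switch only
    list(baseline = base_row("C"),
         therapies = dplyr::bind_rows(
           therapy_row("C", "infliximab", 10),
           therapy_row("C", "adalimumab", 120, dose_intensified = TRUE))),
    ## luminal surgery
    list(baseline = base_row("D"), events = event_row("D", 300)),
    ## non-luminal event never counts
    list(baseline = base_row("E"), events = event_row("E", 100, "other")))
  exp <- classify_exposure(coh)
  expect_equal(exp$early_antitnf, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  ev <- detect_intensification(coh, exp, 365)
  expect_equal(ev$kind, c("second_line_biologic", "any_biologic_escalation",
                          NA, "luminal_surgery", NA))
  expect_equal(ev$day, c(200, 150, NA, 300, NA))
  ## an event at exactly the horizon day counts; after it does not
  expect_equal(detect_intensification(coh, exp, 200)$kind[1],
               "second_line_biologic")
  expect_true(is.na(detect_intensification(coh, exp, 199)$kind[1]))
})

test_that("a biologic inside the early window in the no-early arm is a data error", {
  coh <- assemble_cohort(
    list(baseline = base_row("A"),
         therapies = therapy_row("A", "ustekinumab", 50)))
  exp <- classify_exposure(coh)   # ustekinumab is not an anti-TNF
  expect_false(exp$early_antitnf)
  expect_error(detect_intensification(coh, exp, 365), "data-consistency")
})

test_that("sustained status is tri-state over the scheduled window", {
  rem_pred <- function(v) {
    cc <- categorize_activity(v$wpcdai, v$pga)
    ifelse(is.na(cc), NA, cc == "remission")
  }
  coh <- assemble_cohort(
    list(baseline = base_row("A"),      # remission at 3/6/12
         visits = dplyr::bind_rows(
           visit_row("A", 3, 91, wpcdai = 4), visit_row("A", 6, 183, wpcdai = 2),
           visit_row("A", 12, 365, wpcdai = 0))),
    list(baseline = base_row("B"),      # month 6 missing entirely
         visits = dplyr::bind_rows(
           visit_row("B", 3, 91, wpcdai = 4),
           visit_row("B", 12, 365, wpcdai = 0))),
    list(baseline = base_row("C"),      # mild at month 6 fails the predicate
         visits = dplyr::bind_rows(
           visit_row("C", 3, 91, wpcdai = 4), visit_row("C", 6, 183, wpcdai = 20),
           visit_row("C", 12, 365, wpcdai = 0))),
    list(baseline = base_row("D")))     # no visits in window at all
  st <- sustained_status(coh, rem_pred, 3, 12)
  expect_equal(st$status, c(TRUE, NA, FALSE, NA))
  ## a definite failure beats missingness elsewhere
  coh2 <- assemble_cohort(list(baseline = base_row("E"),
                               visits = visit_row("E", 6, 183, wpcdai = 50)))
  expect_false(sustained_status(coh2, rem_pred, 3, 12)$status)
  ## available-case policy skips missing visits
  expect_equal(sustained_status(coh, rem_pred, 3, 12,
                                missing_policy = "available")$status,
               c(TRUE, TRUE, FALSE, NA))
})

test_that("composite outcome flags follow the definitions", {
  ## sustained remission 3-12, induction steroids only, vedolizumab at day
  ## 200 in the early arm: SSFR holds but SSFR* fails
  p <- remission_patient("A")
  p$therapies <- dplyr::bind_rows(p$therapies,
                                  therapy_row("A", "corticosteroid", 0, 80),
                                  therapy_row("A", "vedolizumab", 200))
  coh <- assemble_cohort(p)
  fl <- derive_outcomes(coh)
  expect_true(fl$ssfr)
  expect_false(fl$ssfr_star)
  expect_true(fl$remission)
  expect_true(fl$sfr)

  ## NCR: strict CRP < 0.5 at the horizon
  p2 <- remission_patient("B")
  p2$visits$crp[p2$visits$nominal_month == 12] <- 0.4
  p3 <- remission_patient("C")
  p3$visits$crp[p3$visits$nominal_month == 12] <- 0.5
  fl2 <- derive_outcomes(assemble_cohort(p2, p3))
  expect_equal(fl2$ncr, c(TRUE, FALSE))

  ## NFR: strict FCP < 250
  p4 <- remission_patient("D")
  p4$visits$fcp[p4$visits$nominal_month == 12] <- 249
  fl4 <- derive_outcomes(assemble_cohort(p4))
  expect_true(fl4$nfr)

  ## a steroid course inside the sustained window breaks SSFR but not
  ## point-in-time remission
  p5 <- remission_patient("E")
  p5$therapies <- dplyr::bind_rows(p5$therapies,
                                   therapy_row("E", "corticosteroid", 100, 160))
  fl5 <- derive_outcomes(assemble_cohort(p5))
  expect_true(fl5$remission)
  expect_false(fl5$ssfr)
  expect_true(fl5$ssfr_star_from6)  # window from month 6 starts after day 183
})

test_that("the outcome hierarchy holds on simulated cohorts", {
  cfg <- sim_config(n = 250, seed = 21)
  coh <- simulate_cohort(cfg, seed = 22)
  fl <- derive_outcomes(coh)
  imp <- function(a, b) !any(a & !b, na.rm = TRUE)  # a TRUE forces b TRUE
  expect_true(imp(fl$ssfr_star, fl$ssfr))
  expect_true(imp(fl$ssfmi_star, fl$ssfmi))
  expect_true(imp(fl$ssfr, fl$ssfmi))
  expect_true(imp(fl$ssfr, fl$sfr))
  expect_true(imp(fl$ssfmi, fl$sfmi))
  expect_true(imp(fl$ncr, fl$remission))
  expect_true(imp(fl$nfr, fl$remission))
  ## SSFMI counts at least match SSFR counts
  expect_gte(sum(fl$ssfmi, na.rm = TRUE), sum(fl$ssfr, na.rm = TRUE))
})

test_that("three-month response uses strict wPCDAI drops with PGA fallback", {
  mk <- function(id, w0, w3, pga0 = NA_character_, pga3 = NA_character_,
                 f0 = NA_real_, f3 = NA_real_) {
    list(baseline = base_row(id, wpcdai = w0, pga = pga0, fcp = f0),
         visits = visit_row(id, 3, 91, wpcdai = w3, pga = pga3, fcp = f3))
  }
  coh <- assemble_cohort(
    mk("A", 51, 10),                       # drop 41 > 37.5: moderate
    mk("B", 51, 33),                       # drop 18 > 17.5: small
    mk("C", 51, 33.5),                     # drop 17.5 exactly: none
    mk("D", NA, NA, "severe", "mild"),     # two PGA categories: moderate
    mk("E", NA, NA, "moderate", "mild"),   # one category: small
    mk("F", 51, NA, "severe", "severe"),   # wPCDAI missing at one end: PGA
    mk("G", 51, 10, f0 = 800, f3 = 400),
    mk("H", 51, 10, f0 = 800, f3 = 420),
    mk("I", 51, 10, f3 = 180))
  resp <- three_month_response(coh)
  expect_equal(resp$response3m[1:6],
               c("moderate", "small", "none", "moderate", "small", "none"))
  ## FCP: >= 50% drop inclusive, or < 250 outright
  expect_equal(resp$fcp_responder3m[7:9], c(TRUE, FALSE, TRUE))
})

test_that("conditional subsets select patients by 3-month status", {
  p1 <- remission_patient("A")           # remission at month 3
  p2 <- remission_patient("B")
  p2$visits$wpcdai[p2$visits$nominal_month == 3] <- 50   # not in remission
  p3 <- remission_patient("C")
  p3$visits$wpcdai[p3$visits$nominal_month == 3] <- NA   # not evaluable
  p3$visits$pga[p3$visits$nominal_month == 3] <- NA
  coh <- assemble_cohort(p1, p2, p3)
  s3 <- status_at_3m(coh)
  expect_equal(s3$sfr3m, c(TRUE, FALSE, NA))
  fl <- derive_outcomes(coh)
  sub <- conditional_subset(fl, s3$sfr3m)
  expect_equal(sub$id, "A")
  expect_equal(nrow(conditional_subset(fl, rep(FALSE, 3))), 0L)
  expect_equal(nrow(conditional_subset(fl, rep(TRUE, 3))), 3L)
})

test_that("derived labels equal generator truth once missingness is removed", {
  cfg <- config_no_missingness(n = 300, seed = 31)
  coh <- simulate_cohort(cfg, seed = 32)
  tr <- cohort_truth(coh)
  fl <- derive_outcomes(coh)
  expect_identical(fl$ssfr_star, tr$ssfr_star_12)
  expect_identical(fl$ssfmi_star, tr$ssfmi_star_12)
  expect_identical(fl$ssfr, tr$ssfr_12)
  expect_identical(fl$ssfmi, tr$ssfmi_12)
  expect_identical(fl$early_antitnf, tr$a)
  ## and at the 2-year horizon
  fl24 <- derive_outcomes(coh, horizon_month = 24)
  expect_identical(fl24$ssfr_star, tr$ssfr_star_24)
  expect_identical(fl24$ssfmi_star, tr$ssfmi_star_24)
})

test_that("denominators shrink as the missingness policy gets stricter", {
  cfg <- sim_config(n = 300, seed = 41)
  coh <- simulate_cohort(cfg, seed = 42)
  strict <- derive_outcomes(coh, missing_policy = "strict")
  avail <- derive_outcomes(coh, missing_policy = "available")
  expect_lte(sum(!is.na(strict$ssfr_star)), sum(!is.na(avail$ssfr_star)))
  expect_lte(sum(!is.na(strict$ssfmi)), sum(!is.na(avail$ssfmi)))
})
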
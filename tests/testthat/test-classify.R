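test_that("wPCDAI categorisation respects the cut points and the PGA fallback", {
  ## boundaries: remission < 12.5; mild 12.5-40; moderate (40, 57.5]; severe above
  expect_equal(
    categorize_activity(c(0, 12.4, 12.5, 40, 40.5, 51, 57.5, 57.6, 127.5)),
    c("remission", "remission", "mild", "mild", "moderate", "moderate",
      "moderate", "severe", "severe"))
  ## PGA is used only where the wPCDAI is missing
  expect_equal(categorize_activity(c(NA, 51), pga = c("severe", "remission")),
               c("severe", "moderate"))
  expect_equal(categorize_activity(NA_real_, pga = "inactive"), "remission")
  ## both missing: missing category, not an error
  expect_true(is.na(categorize_activity(NA_real_, pga = NA_character_)))
  expect_error(categorize_activity(130), "127.5")
  expect_error(categorize_activity(NA, pga = "bogus"), "bogus")
  ## moderate-to-severe indicator
  expect_equal(is_moderate_severe(c("remission", "mild", "moderate", "severe", NA)),
               c(FALSE, FALSE, TRUE, TRUE, NA))
})

test_that("SES-CD categorisation uses <3 / 3-9 / >=10 exactly", {
  expect_equal(categorize_sescd(c(0, 2, 2.9, 3, 9, 10, 30, NA)),
               c("MH", "MH", "MH", "mild", "mild", "moderate-severe",
                 "moderate-severe", NA))
  expect_error(categorize_sescd(-1), "non-negative")
})

test_that("MINI-index banding uses the <3 mucosal-healing boundary", {
  expect_equal(categorize_mini(c(2.9, 3.0, 0, NA), warn = FALSE),
               c("MH", "mild", "MH", NA))
  expect_equal(categorize_mini(c(8, 8.1), warn = FALSE),
               c("mild", "moderate-severe"))
})

test_that("exposure classification applies the inclusive 90-day window", {
  coh <- assemble_cohort(
    list(baseline = base_row("A"),
         therapies = therapy_row("A", "infliximab", 28)),
    list(baseline = base_row("B"),
         therapies = therapy_row("B", "adalimumab", 90)),
    list(baseline = base_row("C"),
         therapies = therapy_row("C", "adalimumab", 91)),
    list(baseline = base_row("D")),  # no anti-TNF at all
    list(baseline = base_row("E"),   # EEN first, then early infliximab
         therapies = dplyr::bind_rows(therapy_row("E", "een", 0, 42),
                                      therapy_row("E", "infliximab", 40))))
  exp <- classify_exposure(coh)
  expect_equal(exp$early_antitnf, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(exp$first_antitnf_day, c(28, 90, 91, NA, 40))
  ## upfront: first induction-class therapy; EEN-first voids it
  expect_equal(exp$upfront, c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("exposure classification is invariant to therapy-row order", {
  th <- dplyr::bind_rows(
    therapy_row("A", "adalimumab", 200),
    therapy_row("A", "infliximab", 30),
    therapy_row("A", "corticosteroid", 5, 60))
  coh1 <- cd_cohort(base_row("A"), therapies = th)
  coh2 <- cd_cohort(base_row("A"), therapies = th[c(3, 1, 2), ])
  expect_identical(classify_exposure(coh1), classify_exposure(coh2))
  expect_equal(classify_exposure(coh1)$first_agent, "infliximab")
})

test_that("POPO derivation matches the component definitions", {
  coh <- assemble_cohort(
    ## extensive: L3 with proximal involvement
    list(baseline = base_row("A", paris_location = "L3", upper_gi = "L4a")),
    list(baseline = base_row("B", paris_location = "L1", upper_gi = "L4a")),
    ## deep colonic ulcer from a colonic "large" sub-score; ileal large
    ## ulcers do not qualify
    list(baseline = base_row("C", ulcer_left_colon = "large")),
    list(baseline = base_row("D", ulcer_ileum = "very_large")),
    ## complicated: B2/B3, or B1 with narrowing and no dilatation
    list(baseline = base_row("E", behaviour = "B2")),
    list(baseline = base_row("F", behaviour = "B1",
                             b1_narrowing_no_dilatation = TRUE)),
    ## deterministic negative fill for perianal and complicated
    list(baseline = base_row("G", perianal = NA, behaviour = NA_character_)))
  popos <- derive_popos(coh)
  expect_equal(popos$extensive_disease[1:2], c(TRUE, FALSE))
  expect_equal(popos$deep_colonic_ulcers[3:4], c(TRUE, FALSE))
  expect_equal(popos$complicated_disease[5:6], c(TRUE, TRUE))
  expect_false(popos$perianal[7])
  expect_false(popos$complicated_disease[7])
})

test_that("growth delay uses a strict -1.5 boundary and any_popo is tri-state", {
  coh <- assemble_cohort(list(baseline = base_row("A", perianal = NA)),
                         list(baseline = base_row("B")))
  z <- tibble::tibble(id = c("A", "B"), hfa_z = c(-1.5, -1.51))
  popos <- derive_popos(coh, hfa_z = z)
  expect_equal(popos$growth_delay, c(FALSE, TRUE))
  expect_equal(popos$any_popo, c(FALSE, TRUE))

  ## monotonicity: adding a true component can never turn any_popo off
  coh2 <- assemble_cohort(list(baseline = base_row("A", perianal = TRUE)))
  p2 <- derive_popos(coh2, hfa_z = tibble::tibble(id = "A", hfa_z = -2))
  expect_true(p2$any_popo)

  ## unresolvable components stay missing for imputation
  coh3 <- assemble_cohort(list(baseline = base_row(
    "A", ulcer_ileum = NA_character_, ulcer_right_colon = NA_character_,
    ulcer_transverse = NA_character_, ulcer_left_colon = NA_character_,
    ulcer_rectum = NA_character_, paris_location = "L3",
    upper_gi = NA_character_)))
  p3 <- derive_popos(coh3)
  expect_true(is.na(p3$deep_colonic_ulcers))
  expect_true(is.na(p3$extensive_disease))
  expect_true(is.na(p3$growth_delay))  # no reference table supplied
})
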
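# inert tests: never positive, never complicating
inert_tests <- function() {
  test_characteristics(
    modality = c("colonoscopy", "sigmoidoscopy", "fit", "fobt"),
    sens_lr = 0, sens_hr = 0, sens_crc = 0, spec = 1, compl = 0,
    whole_colon = c(TRUE, FALSE, TRUE, TRUE),
    distal_fraction = c(1, 0.6, 1, 1))
}

test_that("test characteristics validation enforces the invariants", {
  expect_error(test_characteristics("fit", 0.1, 0.2, 0.7, 0.95, compl = 0.1),
               "stool")
  expect_error(test_characteristics("pcr", 0.1, 0.2, 0.7, 0.95),
               "unknown modality")
  expect_error(test_characteristics("fit", 0.1, 0.2, 1.7, 0.95), "\\[0, 1\\]")
})

test_that("a fully adherent biennial FIT yields offers at 45,47,...,75", {
  s <- strategy_spec("FIT", "fit", 24, adherence = 1)
  tr <- simulate_cohort(cohort_config(50, seed = 1), null_params,
                        zero_lifetable, flat_survival,
                        strategy = s, tests = inert_tests())
  tests <- dplyr::filter(tr$events, event == "test_performed")
  expect_equal(as.integer(table(tests$person)), rep(16L, 50))
  expect_equal(sort(unique(tests$age_months)), seq(45, 75, by = 2) * 12)
})

test_that("no offers arrive before the start age or after the stop age", {
  s <- strategy_spec("FIT", "fit", 24, start_age = 50, stop_age = 60,
                     adherence = 1)
  tr <- simulate_cohort(cohort_config(30, seed = 2), null_params,
                        zero_lifetable, flat_survival,
                        strategy = s, tests = inert_tests())
  ages <- dplyr::filter(tr$events, event == "test_performed")$age_months
  expect_true(all(ages >= 50 * 12 & ages <= 60 * 12))
})

test_that("a negative colonoscopy locks screening out for 120 months", {
  # colonoscopy strategy starting at 50: negative scopes at 50, 60, 70
  s <- strategy_spec("Colo", "colonoscopy", 120, start_age = 50,
                     adherence = 1)
  tr <- simulate_cohort(cohort_config(20, seed = 3), null_params,
                        zero_lifetable, flat_survival,
                        strategy = s, tests = inert_tests())
  ages <- sort(unique(
    dplyr::filter(tr$events, event == "test_performed")$age_months))
  expect_equal(ages, c(50, 60, 70) * 12)

  # FIT with specificity 0: every test positive, follow-up colonoscopy
  # negative -> the stool cadence collapses to the 10-year lockout grid
  tc <- inert_tests()
  tc$spec[tc$modality == "fit"] <- 0
  s2 <- strategy_spec("FIT", "fit", 24, adherence = 1)
  tr2 <- simulate_cohort(cohort_config(20, seed = 4), null_params,
                         zero_lifetable, flat_survival,
                         strategy = s2, tests = tc)
  fit_ages <- sort(unique(dplyr::filter(
    tr2$events, event == "test_performed",
    detail == "fit_screening")$age_months))
  expect_equal(fit_ages, c(45, 55, 65, 75) * 12)
  colo <- dplyr::filter(tr2$events, event == "test_performed",
                        detail == "colonoscopy_followup")
  expect_equal(sort(unique(colo$age_months)), c(45, 55, 65, 75) * 12)
})

test_that("stool test positivity follows sensitivity and specificity", {
  # healthy cohort, specificity 0.95: positives within 3 SE of 5%
  tc <- inert_tests()
  tc$spec[tc$modality == "fit"] <- 0.95
  s <- strategy_spec("FIT", "fit", 24, start_age = 45, stop_age = 45,
                     adherence = 1, followup_adherence = 0)
  n <- 10000
  tr <- simulate_cohort(cohort_config(n, seed = 5), null_params,
                        zero_lifetable, flat_survival, strategy = s,
                        tests = tc)
  pos <- sum(tr$events$event == "positive_test")
  expect_lt(abs(pos - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))

  # everyone in preclinical local at offer age, CRC sensitivity 1:
  # every offer detects
  params <- nh_params(list(
    adenoma_onset = 1, lr_to_hr = 1, hr_to_preclin = 1,
    local_to_regional = 0, regional_to_distant = 0,
    detect_local = 0, detect_regional = 0, detect_distant = 0))
  tc2 <- inert_tests()
  tc2$sens_crc[tc2$modality == "fit"] <- 1
  tc2$sens_crc[tc2$modality == "colonoscopy"] <- 1
  tr2 <- simulate_cohort(cohort_config(500, seed = 6), params,
                         zero_lifetable, flat_survival,
                         strategy = strategy_spec("FIT", "fit", 24,
                                                  adherence = 1),
                         tests = tc2)
  expect_equal(sum(tr2$events$event == "screen_dx"), 500)
  expect_true(all(tr2$persons$dx_age_months == 45 * 12))
})

test_that("detected high-risk adenomas are removed and enter surveillance", {
  # everyone is a high-risk adenoma carrier by 45 and stays one
  params <- nh_params(list(
    adenoma_onset = 1, lr_to_hr = 1, hr_to_preclin = 0,
    local_to_regional = 0, regional_to_distant = 0,
    detect_local = 0, detect_regional = 0, detect_distant = 0))
  tc <- inert_tests()
  tc$sens_hr[tc$modality == "colonoscopy"] <- 1
  s <- strategy_spec("Colo", "colonoscopy", 120, adherence = 1)
  tr <- simulate_cohort(cohort_config(100, seed = 7), params,
                        zero_lifetable, flat_survival, strategy = s,
                        tests = tc)
  polyps <- dplyr::filter(tr$events, event == "polypectomy")
  expect_true(all(polyps$detail == "HR"))
  # surveillance colonoscopies on the 36-month cadence (HR regrows and is
  # found again every time), stopping at the surveillance stop age of 85
  surv <- dplyr::filter(tr$events, event == "test_performed",
                        detail == "colonoscopy_surveillance")
  expect_equal(sort(unique(surv$age_months)), seq(48, 84, by = 3) * 12)
  expect_true(all(surv$age_months <= 85 * 12))
})

test_that("complications never occur when the probability is zero", {
  b <- the_bundle
  tc <- b$tests
  tc$compl <- 0
  tr <- simulate_cohort(cohort_config(5000, seed = 8), b$params,
                        b$lifetable, b$survival,
                        strategy = b$strategies$Colo, tests = tc)
  expect_equal(sum(tr$events$event == "complication"), 0)
})

test_that("adherence 0 reproduces the natural-history trace bit for bit", {
  b <- the_bundle
  cfg <- cohort_config(5000, seed = 9)
  nh <- simulate_cohort(cfg, b$params, b$lifetable, b$survival,
                        tests = b$tests)
  for (nm in c("FIT", "Colo", "Sig")) {
    s <- b$strategies[[nm]]
    s$adherence <- 0
    tr <- simulate_cohort(cfg, b$params, b$lifetable, b$survival,
                          strategy = s, tests = b$tests)
    expect_identical(tr$events, nh$events)
    expect_identical(tr$persons, nh$persons)
  }
})

test_that("a zero-sensitivity perfect-specificity test leaves disease
           outcomes at their natural-history values", {
  b <- the_bundle
  cfg <- cohort_config(5000, seed = 10)
  nh <- simulate_cohort(cfg, b$params, b$lifetable, b$survival,
                        tests = b$tests)
  tr <- simulate_cohort(cfg, b$params, b$lifetable, b$survival,
                        strategy = b$strategies$FIT, tests = inert_tests())
  expect_identical(tr$persons, nh$persons)
  # but the screening arm performed stool tests
  expect_gt(sum(tr$events$event == "test_performed" &
                  startsWith(tr$events$detail, "fit")), 0)
})

test_that("follow-up colonoscopies never exceed positive first-line tests", {
  b <- the_bundle
  cfg <- cohort_config(10000, seed = 11)
  tr <- simulate_cohort(cfg, b$params, b$lifetable, b$survival,
                        strategy = b$strategies$FIT, tests = b$tests)
  pos <- sum(tr$events$event == "positive_test")
  fup <- sum(tr$events$event == "test_performed" &
               tr$events$detail == "colonoscopy_followup")
  expect_equal(fup, pos)  # follow-up adherence is 1 in the base case

  s <- b$strategies$FIT
  s$followup_adherence <- 0.5
  tr2 <- simulate_cohort(cfg, b$params, b$lifetable, b$survival,
                         strategy = s, tests = b$tests)
  pos2 <- sum(tr2$events$event == "positive_test")
  fup2 <- sum(tr2$events$event == "test_performed" &
                tr2$events$detail == "colonoscopy_followup")
  expect_lt(fup2, pos2)
})

test_that("sigmoidoscopy reach scales detection by the distal fraction", {
  # all persons high-risk adenoma carriers; sigmoidoscopy sens 1 but distal
  # fraction 0 -> nothing found; distal fraction 1 -> all found at 45
  params <- nh_params(list(
    adenoma_onset = 1, lr_to_hr = 1, hr_to_preclin = 0,
    local_to_regional = 0, regional_to_distant = 0,
    detect_local = 0, detect_regional = 0, detect_distant = 0))
  for (frac in c(0, 1)) {
    tc <- inert_tests()
    tc$sens_hr[tc$modality == "sigmoidoscopy"] <- 1
    tc$sens_hr[tc$modality == "colonoscopy"] <- 1
    tc$distal_fraction[tc$modality == "sigmoidoscopy"] <- frac
    tr <- simulate_cohort(cohort_config(200, seed = 12), params,
                          zero_lifetable, flat_survival,
                          strategy = strategy_spec("Sig", "sigmoidoscopy", 60,
                                                   adherence = 1),
                          tests = tc)
    n_pos <- sum(tr$events$event == "positive_test")
    if (frac == 0) expect_equal(n_pos, 0) else expect_equal(n_pos, 200)
  }
})

test_that("the two-phase switch strategy changes modality at the cut age", {
  s <- strategy_spec("FIT-Colo", c("fit", "colonoscopy"), c(24, 120),
                     start_age = c(45, 50), stop_age = c(49, 75),
                     adherence = 1)
  tr <- simulate_cohort(cohort_config(50, seed = 13), null_params,
                        zero_lifetable, flat_survival, strategy = s,
                        tests = inert_tests())
  tests <- dplyr::filter(tr$events, event == "test_performed")
  fit_ages <- sort(unique(tests$age_months[startsWith(tests$detail, "fit")]))
  colo_ages <- sort(unique(
    tests$age_months[startsWith(tests$detail, "colonoscopy")]))
  expect_equal(fit_ages, c(45, 47, 49) * 12)
  expect_equal(colo_ages, c(50, 60, 70) * 12)
})
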
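test_that("null dynamics keep everyone healthy through the horizon", {
  cfg <- cohort_config(1000, seed = 4)
  tr <- simulate_cohort(cfg, null_params, zero_lifetable, flat_survival)
  expect_equal(nrow(tr$events), 0)
  expect_true(all(tr$persons$final_state == "Healthy"))
  expect_true(all(is.na(tr$persons$death_age_months)))
  expect_equal(unname(tr$occupancy[, "Healthy"]), rep(1000L, 961))
})

test_that("identical seeds reproduce identical traces", {
  cfg <- cohort_config(2000, seed = 77)
  b <- the_bundle
  t1 <- simulate_cohort(cfg, b$params, b$lifetable, b$survival)
  t2 <- simulate_cohort(cfg, b$params, b$lifetable, b$survival)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$occupancy, t2$occupancy)
  t3 <- simulate_cohort(cohort_config(2000, seed = 78), b$params,
                        b$lifetable, b$survival)
  expect_false(identical(t1$events, t3$events))
})

test_that("occupancy conserves the cohort and death states absorb", {
  cfg <- cohort_config(3000, seed = 5)
  b <- the_bundle
  tr <- simulate_cohort(cfg, b$params, b$lifetable, b$survival)
  expect_true(all(rowSums(tr$occupancy) == 3000))
  dead <- tr$occupancy[, "DeathCRC"] + tr$occupancy[, "DeathOther"]
  expect_true(all(diff(dead) >= 0))  # no resurrection
})

test_that("per-person events are non-decreasing in age and deaths terminal", {
  cfg <- cohort_config(2000, seed = 11)
  b <- the_bundle
  tr <- simulate_cohort(cfg, b$params, b$lifetable, b$survival)
  ok <- tapply(tr$events$age_months, tr$events$person,
               function(a) all(diff(a) >= 0))
  expect_true(all(ok))
  # a death event is each person's last event
  last_ev <- tr$events |>
    dplyr::group_by(person) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  died <- dplyr::filter(tr$events, event %in% c("death_crc", "death_other"))
  expect_setequal(died$person,
                  last_ev$person[last_ev$event %in%
                                   c("death_crc", "death_other")])
})

test_that("CRC death only occurs in diagnosed persons, diagnosis only once", {
  cfg <- cohort_config(20000, seed = 8)
  b <- the_bundle
  tr <- simulate_cohort(cfg, b$params, b$lifetable, b$survival)
  crc_deaths <- tr$persons[tr$persons$death_type == "crc", ]
  expect_gt(nrow(crc_deaths), 0)
  expect_true(all(!is.na(crc_deaths$dx_age_months)))
  dx_counts <- table(tr$events$person[tr$events$event %in%
                                        c("symptomatic_dx", "screen_dx")])
  expect_true(all(dx_counts == 1))
})

test_that("a 3-state chain matches its matrix-power closed form", {
  # Healthy -> AdenomaLR -> AdenomaHR with p1, p2 per month, no mortality
  p1 <- 0.02
  p2 <- 0.05
  params <- nh_params(list(
    adenoma_onset = p1, lr_to_hr = p2, hr_to_preclin = 0,
    local_to_regional = 0, regional_to_distant = 0,
    detect_local = 0, detect_regional = 0, detect_distant = 0))
  n <- 10000
  tr <- simulate_cohort(cohort_config(n, seed = 21), params, zero_lifetable,
                        flat_survival)
  M <- matrix(c(1 - p1, p1, 0,
                0, 1 - p2, p2,
                0, 0, 1), 3, 3, byrow = TRUE)
  v <- c(1, 0, 0)
  for (cyc in 1:120) {
    v <- as.vector(v %*% M)
    obs <- tr$occupancy[cyc + 1, c("Healthy", "AdenomaLR", "AdenomaHR")] / n
    se <- sqrt(v * (1 - v) / n)
    expect_true(all(abs(obs - v) <= 3 * pmax(se, 1e-9) + 3 / n),
                label = paste("cycle", cyc))
  }
})

test_that("cancer mortality stops 120 months after diagnosis", {
  # force immediate preclinical distant cancer and detection, huge cancer
  # hazard: everyone alive at 121+ months post-diagnosis faces no crc risk
  params <- nh_params(list(
    adenoma_onset = 1, lr_to_hr = 1, hr_to_preclin = 1,
    local_to_regional = 0, regional_to_distant = 0,
    detect_local = 1, detect_regional = 0, detect_distant = 0))
  sv <- tidyr::expand_grid(stage = c("local", "regional", "distant"),
                           year = 1:10)
  sv$qx_cancer <- ifelse(sv$year <= 9, 0, 0.9)
  tr <- simulate_cohort(cohort_config(4000, seed = 3), params,
                        zero_lifetable, sv)
  # diagnoses all happen at age 243 months (three forced transitions, then
  # detection); year-10 hazard kills many, but any survivor of the window
  # never dies after month 120 post-diagnosis
  deaths <- tr$persons$death_age_months[tr$persons$death_type == "crc"]
  expect_gt(length(deaths), 0)
  expect_true(all(deaths - tr$persons$dx_age_months[
    tr$persons$death_type == "crc"] <= 120))
  survivors <- tr$persons$death_type == "alive"
  expect_gt(sum(survivors), 0)
})

test_that("incidence and stage summaries compute person-time correctly", {
  cfg <- cohort_config(100, seed = 2)
  # hand-checkable: zero diagnoses
  tr0 <- simulate_cohort(cfg, null_params, zero_lifetable, flat_survival)
  s0 <- incidence_and_stage_summary(tr0)
  expect_true(s0$flagged)
  expect_true(all(s0$incidence$rate_per_100k == 0))
  expect_true(all(is.na(s0$stage_distribution$fraction)))

  b <- the_bundle
  tr <- simulate_cohort(cohort_config(30000, seed = 13), b$params,
                        b$lifetable, b$survival)
  s <- incidence_and_stage_summary(tr)
  expect_false(s$flagged)
  expect_equal(sum(s$stage_distribution$fraction), 1)
  # incidence curve rises with age over the adult range of the fixture
  rates <- s$incidence$rate_per_100k[s$incidence$age_band_start >= 30 &
                                       s$incidence$age_band_start <= 80]
  expect_true(all(diff(rates) > 0))
})
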
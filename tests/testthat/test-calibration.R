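test_that("objective is zero at self-consistent targets and scales in weights", {
  b <- the_bundle
  expect_equal(calibration_objective(b$params, b$targets, b$lifetable), 0)

  # single incidence target, hand arithmetic: model 150 vs target 100 -> 0.25
  tg <- tibble::tibble(target_class = "incidence", key = "60",
                       value = 100, weight = 1)
  fw <- forward_targets(b$params, b$lifetable)
  model <- fw$incidence$rate_per_100k[fw$incidence$age_band_start == 60]
  got <- calibration_objective(b$params, tg, b$lifetable)
  expect_equal(got, ((model - 100) / 100)^2)

  # doubling all weights doubles the score
  set.seed(42)
  for (k in 1:3) {
    p <- b$params
    p$monthly_probability <- p$monthly_probability * runif(nrow(p), 0.7, 1.4)
    t1 <- calibration_objective(p, b$targets, b$lifetable)
    tg2 <- dplyr::mutate(b$targets, weight = weight * 2)
    expect_equal(calibration_objective(p, tg2, b$lifetable), 2 * t1,
                 tolerance = 1e-12)
  }
})

test_that("objective rejects targets outside the horizon", {
  tg <- tibble::tibble(target_class = "incidence", key = "150",
                       value = 10, weight = 1)
  expect_error(calibration_objective(the_bundle$params, tg,
                                     the_bundle$lifetable), "horizon")
})

test_that("proposals perturb only masked parameters on the logit scale", {
  p <- the_bundle$params
  expect_identical(propose_params(p, 0, "adenoma_onset"), p)
  expect_error(propose_params(p, 0.1, character(0)), "non-empty")

  set.seed(1)
  q <- propose_params(p, 0.1, c("detect_local"))
  moved <- p$parameter == "detect_local"
  expect_identical(q$monthly_probability[!moved],
                   p$monthly_probability[!moved])
  expect_false(any(q$monthly_probability[moved] ==
                     p$monthly_probability[moved]))

  # logit arithmetic: a +0.1 step from 0.5 lands on 1/(1+exp(-0.1))
  p5 <- p
  p5$monthly_probability[1] <- 0.5
  x <- crcscreen:::.logit(0.5) + 0.1
  expect_equal(crcscreen:::.inv_logit(x), 0.52498, tolerance = 1e-4)

  # proposals always stay strictly inside (0, 1)
  set.seed(2)
  cur <- p
  for (k in 1:500) {
    cur <- propose_params(cur, 1.5, nh_param_names())
    expect_true(all(cur$monthly_probability > 0 &
                      cur$monthly_probability < 1))
  }
})

test_that("zero-iteration annealing returns the initial parameters", {
  b <- the_bundle
  fit <- anneal(b$targets, anneal_schedule(max_iter = 0, seed = 1),
                b$params, lifetable = b$lifetable)
  expect_equal(fit$best_params, b$params)
  expect_equal(fit$best_objective,
               calibration_objective(b$params, b$targets, b$lifetable))
  expect_equal(nrow(fit$trajectory), 0)
})

test_that("annealing is reproducible under a seed", {
  b <- the_bundle
  set.seed(9)
  start <- b$params
  start$monthly_probability <- start$monthly_probability *
    runif(nrow(start), 0.8, 1.25)
  sch <- anneal_schedule(max_iter = 400, seed = 5)
  f1 <- anneal(b$targets, sch, start, lifetable = b$lifetable,
               polish_maxit = 0)
  f2 <- anneal(b$targets, sch, start, lifetable = b$lifetable,
               polish_maxit = 0)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_identical(f1$best_params, f2$best_params)
})

test_that("stages never move parameters outside their mask", {
  b <- the_bundle
  set.seed(10)
  start <- b$params
  start$monthly_probability <- start$monthly_probability *
    runif(nrow(start), 0.8, 1.25)
  # stage 1 only, no polish: everything but adenoma_onset must be untouched
  fit <- anneal(b$targets, anneal_schedule(max_iter = 200, seed = 2), start,
                stage_masks = default_stage_masks()[1],
                lifetable = b$lifetable, polish_maxit = 0)
  sel <- start$parameter != "adenoma_onset"
  expect_identical(fit$best_params$monthly_probability[sel],
                   start$monthly_probability[sel])
})

test_that("best-so-far objective is non-increasing within a chain stage", {
  b <- the_bundle
  set.seed(11)
  start <- b$params
  start$monthly_probability <- start$monthly_probability *
    runif(nrow(start), 0.7, 1.4)
  fit <- anneal(b$targets, anneal_schedule(max_iter = 600, seed = 3), start,
                lifetable = b$lifetable, polish_maxit = 0, restarts = 1)
  for (s in unique(fit$trajectory$stage)) {
    tr <- fit$trajectory[fit$trajectory$stage == s, ]
    expect_true(all(diff(tr$best_objective) <= 1e-15))
  }
})

test_that("near-zero temperature accepts only improving moves", {
  b <- the_bundle
  set.seed(12)
  start <- b$params
  start$monthly_probability <- start$monthly_probability *
    runif(nrow(start), 0.7, 1.4)
  fit <- anneal(b$targets,
                anneal_schedule(t0 = 1e-12, max_iter = 400, seed = 4),
                start, lifetable = b$lifetable, polish_maxit = 0,
                restarts = 1)
  acc <- fit$trajectory[fit$trajectory$accepted == 1, ]
  expect_true(all(diff(acc$objective[acc$stage == 1]) <= 1e-15))
})

test_that("holdout validation reports deviations and flags them", {
  b <- the_bundle
  rep0 <- validate_calibration(b$params, b$targets, b$lifetable)
  expect_true(all(rep0$relative_deviation < 1e-5))
  expect_false(any(rep0$flagged))

  off <- b$params
  off$monthly_probability <- off$monthly_probability * 1.6
  rep1 <- validate_calibration(off, b$targets, b$lifetable, tolerance = 0.05)
  expect_true(any(rep1$flagged))

  empty <- validate_calibration(b$params, b$targets[0, ], b$lifetable)
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "empty_holdout"))
})
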
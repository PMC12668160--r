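small_cfg <- cohort_config(1500, seed = 30)

test_that("method-of-moments samplers match the stated algebra", {
  # gamma mean 100, se 20 -> shape 25, scale 4
  g <- fit_distribution("gamma", 100, 20)
  set.seed(1)
  draws <- g(1e5)
  expect_lt(abs(mean(draws) - 100) / 100, 0.01)
  expect_lt(abs(stats::var(draws) - 400) / 400, 0.05)

  # beta mean 0.5, se 0.1 -> alpha = beta = 12
  b <- fit_distribution("beta", 0.5, 0.1)
  set.seed(2)
  draws <- b(1e5)
  expect_lt(abs(mean(draws) - 0.5), 0.005)
  expect_lt(abs(stats::sd(draws) - 0.1), 0.005)

  # degenerate limit
  d <- fit_distribution("gamma", 7, 0)
  expect_equal(d(5), rep(7, 5))
  expect_error(fit_distribution("beta", 0.5, 0.9), "infeasible")
  expect_error(fit_distribution("beta", 1.2, 0.1), "inside")
})

test_that("bundle parameter paths read and write consistently", {
  b <- the_bundle
  for (path in c("cost.fit", "test.fit.sens_crc", "weight.cancer_distant",
                 "strategy.adherence")) {
    v0 <- get_bundle_param(b, path)
    b2 <- set_bundle_param(b, path, v0 * 0.5)
    expect_equal(get_bundle_param(b2, path), v0 * 0.5)
  }
  expect_error(set_bundle_param(b, "cost.nonsense", 1), "unknown")
  expect_error(get_bundle_param(b, "what.is.this"), "unknown")
})

test_that("tornado: degenerate ranges give zero width, invalid ranges error
           before any run, order of input does not matter", {
  b <- the_bundle
  base_fit <- get_bundle_param(b, "cost.fit")
  ranges <- tibble::tibble(
    path = c("cost.fit", "cost.colonoscopy", "test.fit.spec"),
    low = c(base_fit, 80, 0.90),
    high = c(base_fit, 200, 0.99))
  dsa <- one_way_dsa(b, ranges, c("NH", "FIT"), small_cfg)
  expect_equal(dsa$width[dsa$path == "cost.fit"], 0)
  expect_true(all(diff(dsa$width) <= 0))

  dsa_shuffled <- one_way_dsa(b, ranges[c(3, 1, 2), ], c("NH", "FIT"),
                              small_cfg)
  expect_equal(as.data.frame(dsa_shuffled), as.data.frame(dsa))

  bad <- tibble::tibble(path = "cost.fit", low = base_fit * 2,
                        high = base_fit * 3)
  expect_error(one_way_dsa(b, bad, c("NH", "FIT"), small_cfg),
               "low <= base <= high")
})

test_that("raising the FIT unit cost raises the FIT-vs-NH ICER", {
  b <- the_bundle
  base_fit <- get_bundle_param(b, "cost.fit")
  ranges <- tibble::tibble(path = "cost.fit", low = base_fit,
                           high = base_fit * 4)
  dsa <- one_way_dsa(b, ranges, c("NH", "FIT"), small_cfg)
  expect_gt(dsa$icer_high, dsa$icer_low)
})

test_that("PSA with zero standard errors reproduces the base case exactly", {
  b <- the_bundle
  dists <- psa_distributions(b)
  dists$se <- 0
  psa <- run_psa(b, dists, n_iter = 2, seed = 4, config = small_cfg)
  base <- crcscreen:::.evaluate_bundle(b, small_cfg)
  for (it in 1:2) {
    got <- psa$iterations[psa$iterations$iter == it, ]
    got <- got[match(base$table$strategy, got$strategy), ]
    expect_identical(got$cost, base$table$cost)
    expect_identical(got$effect, base$table$effect)
  }
  # step-function acceptability curve: one winner everywhere per wtp
  expect_true(all(psa$ceac$fraction %in% c(0, 1)))
})

test_that("the acceptability curve is normalised and degenerates correctly
           at zero willingness to pay", {
  b <- the_bundle
  dists <- psa_distributions(b, se_frac = 0.25)
  psa <- run_psa(b, dists, n_iter = 20, wtp_grid = c(0, 5000, 11692, 30000),
                 seed = 5, config = small_cfg)
  sums <- psa$ceac |>
    dplyr::group_by(wtp) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, 4), tolerance = 1e-12)
  # at wtp 0 the least costly strategy wins every iteration
  at0 <- psa$ceac[psa$ceac$wtp == 0, ]
  expect_equal(at0$fraction[at0$strategy == "NH"], 1)
  # reproducibility under the seed
  psa2 <- run_psa(b, dists, n_iter = 20,
                  wtp_grid = c(0, 5000, 11692, 30000),
                  seed = 5, config = small_cfg)
  expect_identical(psa$iterations, psa2$iterations)
})

test_that("incidence scaling hits its target multiple by bisection", {
  b <- the_bundle
  base <- forward_targets(b$params, b$lifetable)$lifetime_incidence
  for (scale in c(0.5, 2)) {
    scaled <- scale_incidence_params(b$params, b$lifetable, scale)
    got <- forward_targets(scaled, b$lifetable)$lifetime_incidence
    expect_lt(abs(got - scale * base) / (scale * base), 0.01)
    # only onset rows moved
    other <- b$params$parameter != "adenoma_onset"
    expect_identical(scaled$monthly_probability[other],
                     b$params$monthly_probability[other])
  }
})

test_that("scenario runner: empty list gives the base case only; start-age
           scenarios leave the natural-history row untouched", {
  b <- the_bundle
  out0 <- run_scenarios(b, list(), small_cfg)
  expect_named(out0, "base")

  out <- run_scenarios(
    b, list(list(name = "start40", start_age = 40),
            list(name = "start50", start_age = 50)),
    small_cfg)
  nh_rows <- lapply(out, function(cea) {
    cea$table[cea$table$strategy == "NH",
              c("cost", "effect", "crc_cases_per_100k")]
  })
  expect_equal(nh_rows$start40, nh_rows$base)
  expect_equal(nh_rows$start50, nh_rows$base)
})

test_that("the switch scenario adds a two-phase strategy to the table", {
  b <- the_bundle
  out <- run_scenarios(b, list(list(name = "switch",
                                    fit_colo_switch = TRUE)), small_cfg)
  expect_true("FIT-Colo" %in% out$switch$table$strategy)
})
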
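# the published base-case table this package's decision logic is checked
# against: per-person lifetime costs and cumulative DALYs averted vs no
# screening, reconstructed from the incremental column
table1 <- tibble::tibble(
  strategy = c("NH", "FIT", "FOBT", "Colo", "Sig"),
  cost = c(73.89, 101.39, 106.46, 171.43, 177.90),
  effect = c(0, 0.0129, 0.0092, 0.0183, 0.0142))

test_that("ICER arithmetic handles zero and reproduces printed ratios within
           display rounding", {
  expect_equal(icer(0, 0.01), 0)
  expect_true(is.na(icer(5, 0)))
  # printed increments carry 2 and 4 decimals; the printed ICERs must lie
  # inside the interval the rounded inputs allow
  expect_gte(2134.74, 27.495 / 0.01295)
  expect_lte(2134.74, 27.505 / 0.01285)
  expect_equal(icer(27.50, 0.0129), 2131.78, tolerance = 1e-4)
  expect_gte(12903.51, 70.035 / 0.00545)
  expect_lte(12903.51, 70.045 / 0.00535)
  expect_equal(icer(70.04, 0.0054), 12970.37, tolerance = 1e-4)
})

test_that("the published strategies split into the known frontier", {
  fr <- find_frontier(table1)
  expect_setequal(fr$strategy[fr$on_frontier], c("NH", "FIT", "Colo"))
  expect_true(fr$strictly_dominated[fr$strategy == "FOBT"])
  expect_true(fr$strictly_dominated[fr$strategy == "Sig"])
  icers <- fr$icer[fr$on_frontier]
  expect_true(all(diff(icers[!is.na(icers)]) > 0))
  # frontier ICERs match the printed ones within display rounding
  expect_equal(fr$icer[fr$strategy == "FIT"], 2131.78, tolerance = 1e-4)
  expect_equal(fr$icer[fr$strategy == "Colo"], 12970.37, tolerance = 1e-4)
})

test_that("the decision rule picks FIT at the country threshold", {
  fr <- find_frontier(table1)
  expect_equal(decide(fr, 11692), "FIT")
  expect_equal(decide(fr, 20000), "Colo")
  expect_equal(decide(fr, 100), "NH")
})

test_that("single strategies and duplicates are handled", {
  one <- find_frontier(tibble::tibble(strategy = "A", cost = 5, effect = 1))
  expect_true(one$on_frontier)
  expect_true(is.na(one$icer))
  expect_error(find_frontier(tibble::tibble(strategy = c("A", "A"),
                                            cost = 1:2, effect = 1:2)),
               "duplicate")
  dup <- find_frontier(tibble::tibble(strategy = c("A", "B"),
                                      cost = c(1, 1), effect = c(1, 1)))
  expect_true(all(dup$duplicate))
})

test_that("frontier agrees with a brute-force hull oracle on random inputs", {
  # oracle: a strategy is on the frontier iff it maximises net monetary
  # benefit (effect * wtp - cost) for some willingness to pay >= 0 --
  # equivalently it sits on the upper-left convex hull
  brute_frontier <- function(tb) {
    nmb_winner <- function(w) {
      nmb <- tb$effect * w - tb$cost
      tb$strategy[nmb >= max(nmb) - 1e-12]
    }
    wtps <- c(0, 10^seq(-3, 9, length.out = 4000))
    sort(unique(unlist(lapply(wtps, nmb_winner))))
  }
  set.seed(123)
  for (k in 1:100) {
    n <- sample(2:8, 1)
    tb <- tibble::tibble(strategy = paste0("S", 1:n),
                         cost = round(runif(n, 0, 100), 2),
                         effect = round(runif(n, 0, 1), 3))
    fr <- find_frontier(tb)
    got <- sort(fr$strategy[fr$on_frontier])
    expect_setequal(got, brute_frontier(tb))
  }
})

test_that("decision is monotone in willingness to pay", {
  set.seed(321)
  for (k in 1:20) {
    n <- sample(3:8, 1)
    tb <- tibble::tibble(strategy = paste0("S", 1:n),
                         cost = runif(n, 0, 100), effect = runif(n))
    fr <- find_frontier(tb)
    eff <- sapply(c(1, 10, 100, 1000, 1e4, 1e5, 1e6), function(w) {
      tb$effect[tb$strategy == decide(fr, w)]
    })
    expect_true(all(diff(eff) >= 0))
  }
})

test_that("frontier membership is invariant to positive affine cost rescaling", {
  fr0 <- find_frontier(table1)
  resc <- dplyr::mutate(table1, cost = 3.7 * cost + 12)
  fr1 <- find_frontier(resc)
  expect_equal(fr1$on_frontier[order(fr1$strategy)],
               fr0$on_frontier[order(fr0$strategy)])
})

test_that("summarize_strategy arithmetic on hand-built traces", {
  b <- the_bundle
  # 10 persons, 2 CRC cases vs a reference with 4 -> 50% averted
  mk <- function(n_cases) {
    pers <- person_row(1:10)
    pers$dx_age_months[seq_len(n_cases)] <- 600L
    pers$dx_stage[seq_len(n_cases)] <- "local"
    ev <- tibble::tibble(person = seq_len(n_cases),
                         age_months = 600L,
                         event = "symptomatic_dx", detail = "local")
    hand_trace(ev, pers)
  }
  two <- mk(2)
  four <- mk(4)
  row <- summarize_strategy(two, b$costs, b$weights, reference = four)
  expect_equal(row$pct_cases_averted, 50)
  expect_equal(row$crc_cases_per_100k, 2 / 10 * 1e5)
  self <- summarize_strategy(four, b$costs, b$weights, reference = four)
  expect_equal(self$effect, 0)
  expect_equal(self$pct_cases_averted, 0)
  expect_error(summarize_strategy(two, b$costs, b$weights,
                                  reference = hand_trace(empty_events,
                                                         person_row(1:3))),
               "cohort sizes")
})

test_that("cea_analysis assembles the table, frontier and decision", {
  b <- the_bundle
  cfg <- cohort_config(4000, seed = 17)
  traces <- c(
    list(NH = simulate_cohort(cfg, b$params, b$lifetable, b$survival,
                              tests = b$tests)),
    lapply(b$strategies[c("FIT", "Colo")], function(s) {
      simulate_cohort(cfg, b$params, b$lifetable, b$survival, strategy = s,
                      tests = b$tests)
    }))
  cea <- cea_analysis(traces, "NH", b$costs, b$weights)
  expect_equal(nrow(cea$table), 3)
  expect_equal(cea$table$effect[cea$table$strategy == "NH"], 0)
  expect_true("NH" %in% cea$frontier)
  expect_true(cea$optimal %in% cea$table$strategy)
  td <- tidy(cea)
  expect_s3_class(td, "tbl_df")
  gl <- glance(cea)
  expect_equal(gl$n_strategies, 3)
})
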
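#' Get or set a model input by dotted parameter path
#'
#' Sensitivity analyses address inputs inside a fixture bundle by path:
#' `cost.<item>` (unit costs), `test.<modality>.<field>` (test operating
#' characteristics, `field` one of `sens_lr`, `sens_hr`, `sens_crc`, `spec`,
#' `compl`, `distal_fraction`), `weight.<item>` (disability weights) and
#' `strategy.<field>` (`adherence`, `followup_adherence`, applied to every
#' strategy).
#'
#' @param bundle A fixture bundle ([make_fixture_bundle()]).
#' @param path Dotted parameter path.
#' @param value Replacement value.
#' @return `get_bundle_param`: the current value; `set_bundle_param`: the
#'   modified bundle.
#' @export
get_bundle_param <- function(bundle, path) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  switch(p[1],
    cost = bundle$costs$cost[match(p[2], bundle$costs$item)],
    test = bundle$tests[[p[3]]][match(p[2], bundle$tests$modality)],
    weight = bundle$weights$weight[match(p[2], bundle$weights$item)],
    strategy = bundle$strategies[[1]][[p[2]]],
    stop("unknown parameter path: ", path, call. = FALSE))
}

#' @rdname get_bundle_param
#' @export
set_bundle_param <- function(bundle, path, value) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (p[1] == "cost") {
    i <- match(p[2], bundle$costs$item)
    if (is.na(i)) stop("unknown cost item: ", p[2], call. = FALSE)
    bundle$costs$cost[i] <- value
  } else if (p[1] == "test") {
    i <- match(p[2], bundle$tests$modality)
    if (is.na(i) || !p[3] %in% names(bundle$tests)) {
      stop("unknown test parameter: ", path, call. = FALSE)
    }
    bundle$tests[[p[3]]][i] <- value
  } else if (p[1] == "weight") {
    i <- match(p[2], bundle$weights$item)
    if (is.na(i)) stop("unknown weight item: ", p[2], call. = FALSE)
    bundle$weights$weight[i] <- value
  } else if (p[1] == "strategy") {
    bundle$strategies <- lapply(bundle$strategies, function(s) {
      s[[p[2]]] <- value
      s
    })
  } else {
    stop("unknown parameter path: ", path, call. = FALSE)
  }
  bundle
}

# simulate the strategies named in `which` (plus NH) and return the CEA
.evaluate_bundle <- function(bundle, config, which = NULL,
                             dsc = discount_spec(), wtp = 11692) {
  strategies <- bundle$strategies
  if (!is.null(which)) strategies <- strategies[which]
  traces <- c(
    list(NH = simulate_cohort(config, bundle$params, bundle$lifetable,
                              bundle$survival, tests = bundle$tests)),
    lapply(strategies, function(s) {
      simulate_cohort(config, bundle$params, bundle$lifetable,
                      bundle$survival, strategy = s, tests = bundle$tests)
    }))
  cea_analysis(traces, "NH", bundle$costs, bundle$weights, dsc, wtp)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies one parameter at a time to its low and high value, re-runs the two
#' comparison strategies under common random numbers, and reports the ICER of
#' the pair at each end, sorted by bar width. Range invariants
#' (`low <= base <= high`) are checked before any simulation.
#'
#' @param bundle Fixture bundle.
#' @param ranges Tibble with columns `path`, `low`, `high`.
#' @param comparison Length-2 character: reference and comparator strategy
#'   (`"NH"` allowed as reference).
#' @param config A [cohort_config()].
#' @param dsc A [discount_spec()].
#' @return A `crc_dsa` tibble: `path`, `low`, `high`, `icer_low`,
#'   `icer_high`, `width`, sorted by descending width; `icer_base` in the
#'   attribute `"icer_base"`.
#' @export
one_way_dsa <- function(bundle, ranges, comparison = c("NH", "FIT"), config,
                        dsc = discount_spec()) {
  stopifnot(all(c("path", "low", "high") %in% names(ranges)),
            length(comparison) == 2)
  for (k in seq_len(nrow(ranges))) {
    base <- get_bundle_param(bundle, ranges$path[k])
    if (!(ranges$low[k] <= base && base <= ranges$high[k])) {
      stop("range for ", ranges$path[k],
           " violates low <= base <= high", call. = FALSE)
    }
  }
  pair_icer <- function(b) {
    cea <- .evaluate_bundle(b, config, which = setdiff(comparison, "NH"),
                            dsc = dsc)
    tab <- cea$table
    i <- match(comparison[2], tab$strategy)  # comparator
    j <- match(comparison[1], tab$strategy)  # reference
    icer(tab$cost[i] - tab$cost[j], tab$effect[i] - tab$effect[j])
  }
  base_icer <- pair_icer(bundle)
  rows <- purrr::map(seq_len(nrow(ranges)), function(k) {
    lo <- pair_icer(set_bundle_param(bundle, ranges$path[k], ranges$low[k]))
    hi <- pair_icer(set_bundle_param(bundle, ranges$path[k], ranges$high[k]))
    tibble::tibble(path = ranges$path[k], low = ranges$low[k],
                   high = ranges$high[k], icer_low = lo, icer_high = hi,
                   width = abs(hi - lo))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$width))
  attr(out, "icer_base") <- base_icer
  class(out) <- c("crc_dsa", class(out))
  out
}

#' Method-of-moments samplers for probabilistic sensitivity analysis
#'
#' Costs are Gamma-distributed (`shape = mean^2/se^2`, `scale = se^2/mean`);
#' probabilities and disability weights are Beta-distributed with matching
#' mean and standard error. `se = 0` gives a degenerate sampler returning the
#' mean. A Beta mean/SE pair outside the feasible region
#' (`se^2 < mean (1 - mean)`) is an error reporting the feasible bound.
#'
#' @param family `"gamma"` or `"beta"`.
#' @param mean Distribution mean (base-case value).
#' @param se Standard error; default 20\% of the mean.
#' @return Function of `n` returning `n` draws.
#' @export
fit_distribution <- function(family = c("gamma", "beta"), mean, se = 0.2 * mean) {
  family <- match.arg(family)
  stopifnot(se >= 0)
  if (se == 0) return(function(n) rep(mean, n))
  if (family == "gamma") {
    stopifnot(mean > 0)
    shape <- mean^2 / se^2
    scale <- se^2 / mean
    function(n) stats::rgamma(n, shape = shape, scale = scale)
  } else {
    if (mean <= 0 || mean >= 1) {
      stop("beta mean must lie strictly inside (0, 1)", call. = FALSE)
    }
    if (se^2 >= mean * (1 - mean)) {
      stop("beta se infeasible; need se < ",
           signif(sqrt(mean * (1 - mean)), 6), call. = FALSE)
    }
    nu <- mean * (1 - mean) / se^2 - 1
    function(n) stats::rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
  }
}

#' Default PSA distribution table for a bundle
#'
#' Gamma distributions on every unit cost, Beta on the test operating
#' characteristics and the disability weights, each with standard error a
#' fixed fraction of the mean (default 20\%). Degenerate base values (0 or 1
#' probabilities, zero costs) are held fixed.
#'
#' @param bundle Fixture bundle.
#' @param se_frac Standard error as a fraction of the mean.
#' @return Tibble `path`, `family`, `mean`, `se`.
#' @export
psa_distributions <- function(bundle, se_frac = 0.2) {
  rows <- list()
  for (it in bundle$costs$item) {
    m <- get_bundle_param(bundle, paste0("cost.", it))
    if (m > 0) rows[[length(rows) + 1]] <-
        tibble::tibble(path = paste0("cost.", it), family = "gamma",
                       mean = m, se = se_frac * m)
  }
  for (mod in bundle$tests$modality) {
    for (f in c("sens_lr", "sens_hr", "sens_crc", "spec", "compl")) {
      m <- get_bundle_param(bundle, paste0("test.", mod, ".", f))
      if (m > 0 && m < 1) rows[[length(rows) + 1]] <-
          tibble::tibble(path = paste0("test.", mod, ".", f), family = "beta",
                         mean = m, se = se_frac * min(m, 1 - m))
    }
  }
  for (it in bundle$weights$item) {
    m <- get_bundle_param(bundle, paste0("weight.", it))
    if (m > 0 && m < 1) rows[[length(rows) + 1]] <-
        tibble::tibble(path = paste0("weight.", it), family = "beta",
                       mean = m, se = se_frac * min(m, 1 - m))
  }
  dplyr::bind_rows(rows)
}

#' Probabilistic sensitivity analysis
#'
#' Each iteration draws one joint parameter set from the distribution table,
#' re-simulates every strategy (and natural history) under the same cohort
#' random streams to isolate parameter uncertainty, and records mean cost and
#' mean DALYs averted. Optimality at each willingness-to-pay point is decided
#' by highest net monetary benefit (`effect x WTP - cost`). Natural-history
#' transition probabilities stay fixed at their calibrated values.
#'
#' @param bundle Fixture bundle.
#' @param distributions Tibble from [psa_distributions()] (or hand-built).
#' @param n_iter Number of PSA iterations.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @param seed Seed for the parameter draws (the cohort seed lives in
#'   `config`).
#' @param config A [cohort_config()].
#' @param dsc A [discount_spec()].
#' @param base_wtp Threshold at which the headline optimal fraction is read.
#' @return A `crc_psa` list: `iterations` (tibble iter x strategy with cost,
#'   effect), `ceac` (tibble wtp x strategy with fraction optimal),
#'   `fraction_optimal_at_base` (tibble), `n_redraws`.
#' @export
run_psa <- function(bundle, distributions, n_iter = 200,
                    wtp_grid = seq(0, 30000, by = 2500), seed = 1L, config,
                    dsc = discount_spec(), base_wtp = 11692) {
  stopifnot(n_iter >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  samplers <- purrr::pmap(distributions, function(path, family, mean, se) {
    fit_distribution(family, mean, se)
  })
  upper <- ifelse(distributions$family == "beta", 1, Inf)
  n_redraws <- 0L

  iters <- purrr::map(seq_len(n_iter), function(it) {
    b <- bundle
    for (k in seq_along(samplers)) {
      v <- samplers[[k]](1)
      while (!is.finite(v) || v < 0 || v >= upper[k] && upper[k] == 1) {
        n_redraws <<- n_redraws + 1L
        v <- samplers[[k]](1)
      }
      b <- set_bundle_param(b, distributions$path[k], v)
    }
    cea <- .evaluate_bundle(b, config, dsc = dsc, wtp = base_wtp)
    dplyr::mutate(cea$table[, c("strategy", "cost", "effect")], iter = it)
  }) |> dplyr::bind_rows()

  ceac <- purrr::map(wtp_grid, function(w) {
    iters |>
      dplyr::group_by(.data$iter) |>
      dplyr::summarise(
        winner = .data$strategy[which.max(.data$effect * w - .data$cost)],
        .groups = "drop") |>
      dplyr::count(.data$winner) |>
      dplyr::mutate(wtp = w, fraction = .data$n / n_iter) |>
      dplyr::select("wtp", strategy = "winner", "fraction")
  }) |>
    dplyr::bind_rows() |>
    tidyr::complete(wtp = wtp_grid,
                    strategy = unique(iters$strategy),
                    fill = list(fraction = 0))

  at_base <- iters |>
    dplyr::group_by(.data$iter) |>
    dplyr::summarise(
      winner = .data$strategy[which.max(.data$effect * base_wtp - .data$cost)],
      .groups = "drop") |>
    dplyr::count(.data$winner) |>
    dplyr::mutate(fraction = .data$n / n_iter) |>
    dplyr::select(strategy = "winner", "fraction")

  structure(list(iterations = iters, ceac = ceac,
                 fraction_optimal_at_base = at_base, base_wtp = base_wtp,
                 n_redraws = n_redraws),
            class = "crc_psa")
}

#' @export
print.crc_psa <- function(x, ...) {
  cat("<crc_psa> ", max(x$iterations$iter), " iterations\n", sep = "")
  print(x$fraction_optimal_at_base)
  invisible(x)
}

#' @export
tidy.crc_psa <- function(x, ...) x$ceac

#' @export
glance.crc_psa <- function(x, ...) {
  best <- x$fraction_optimal_at_base
  best <- best[which.max(best$fraction), ]
  tibble::tibble(n_iter = max(x$iterations$iter), base_wtp = x$base_wtp,
                 optimal = best$strategy, fraction_optimal = best$fraction,
                 n_redraws = x$n_redraws)
}

#' Rescale adenoma onset so lifetime incidence hits a target multiple
#'
#' Finds, by bisection on a common multiplier of the age-banded adenoma-onset
#' probabilities, parameters whose no-screening lifetime incidence (from the
#' deterministic forward operator) equals `scale` times the base value within
#' the stated tolerance.
#'
#' @param params Base parameter table.
#' @param lifetable Annual all-cause lifetable.
#' @param scale Target incidence multiple (e.g. 0.5 or 2).
#' @param tol Relative tolerance on the achieved multiple (default 0.01).
#' @param max_iter Bisection iteration cap (default 60).
#' @return Parameter table with rescaled onset probabilities.
#' @export
scale_incidence_params <- function(params, lifetable, scale, tol = 0.01,
                                   max_iter = 60) {
  base <- forward_targets(params, lifetable)$lifetime_incidence
  target <- scale * base
  f <- function(m) {
    p <- params
    sel <- p$parameter == "adenoma_onset"
    p$monthly_probability[sel] <- pmin(p$monthly_probability[sel] * m, 1)
    forward_targets(p, lifetable)$lifetime_incidence
  }
  lo <- 0.01
  hi <- 100
  for (k in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisect on the log scale
    v <- f(mid)
    if (abs(v - target) / target <= tol) {
      sel <- params$parameter == "adenoma_onset"
      params$monthly_probability[sel] <-
        pmin(params$monthly_probability[sel] * mid, 1)
      return(params)
    }
    if (v < target) lo <- mid else hi <- mid
  }
  stop("incidence-scaling bisection did not converge in ", max_iter,
       " iterations", call. = FALSE)
}

#' Scenario analyses
#'
#' Re-runs the cost-effectiveness analysis under named overrides: screening
#' start age, surveillance stop age, adherence pair, lifetime-incidence
#' scaling (onset multiplier re-solved by bisection), an alternative
#' stage-distribution target (re-running the detection-calibration stage),
#' and the FIT-to-colonoscopy switch strategy.
#'
#' @param bundle Fixture bundle.
#' @param scenarios List of scenario specs; each a list with `name` and any
#'   of `start_age`, `surveillance_stop_age`, `adherence`,
#'   `followup_adherence`, `incidence_scale`, `stage_mix` (3-vector of
#'   local/regional/distant fractions), `fit_colo_switch` (logical).
#' @param config A [cohort_config()].
#' @param dsc,wtp Economic settings.
#' @param anneal_iter Iterations for the detection re-calibration when a
#'   `stage_mix` override is present.
#' @return Named list of `crc_cea` objects (always including `"base"`).
#' @export
run_scenarios <- function(bundle, scenarios = list(), config,
                          dsc = discount_spec(), wtp = 11692,
                          anneal_iter = 600) {
  out <- list(base = .evaluate_bundle(bundle, config, dsc = dsc, wtp = wtp))
  for (sc in scenarios) {
    b <- bundle
    if (!is.null(sc$start_age) || !is.null(sc$surveillance_stop_age) ||
        !is.null(sc$adherence) || !is.null(sc$followup_adherence)) {
      b$strategies <- lapply(b$strategies, function(s) {
        if (!is.null(sc$start_age)) s$start_age[1] <- sc$start_age
        if (!is.null(sc$surveillance_stop_age))
          s$surveillance_stop_age <- sc$surveillance_stop_age
        if (!is.null(sc$adherence)) s$adherence <- sc$adherence
        if (!is.null(sc$followup_adherence))
          s$followup_adherence <- sc$followup_adherence
        s
      })
    }
    if (!is.null(sc$incidence_scale)) {
      b$params <- scale_incidence_params(b$params, b$lifetable,
                                         sc$incidence_scale)
    }
    if (!is.null(sc$stage_mix)) {
      tg <- b$targets
      tg$value[tg$target_class == "stage"] <-
        sc$stage_mix[match(tg$key[tg$target_class == "stage"], .STAGES)]
      fit <- anneal(tg,
                    anneal_schedule(max_iter = anneal_iter, seed = 7L),
                    b$params,
                    stage_masks = default_stage_masks()[3],
                    lifetable = b$lifetable)
      b$params <- fit$best_params
      b$targets <- tg
    }
    if (isTRUE(sc$fit_colo_switch)) {
      ref <- b$strategies[[1]]
      b$strategies <- c(b$strategies, list(
        `FIT-Colo` = strategy_spec(
          "FIT-Colo", c("fit", "colonoscopy"), c(24, 120),
          start_age = c(45, 50), stop_age = c(49, 75),
          adherence = ref$adherence,
          followup_adherence = ref$followup_adherence,
          surveillance_stop_age = ref$surveillance_stop_age)))
    }
    out[[sc$name]] <- .evaluate_bundle(b, config, dsc = dsc, wtp = wtp)
  }
  out
}

#' Adherence-grid surface for the top strategies
#'
#' Sweeps first-line and follow-up adherence for the named strategies and
#' reports the percent reduction in CRC incidence and mortality versus
#' natural history at each grid point.
#'
#' @param bundle Fixture bundle.
#' @param config A [cohort_config()].
#' @param first_line,followup Adherence grids.
#' @param strategies Strategy names to sweep (follow-up only matters for
#'   non-colonoscopy strategies).
#' @return Tibble: strategy, adherence, followup_adherence,
#'   pct_cases_averted, pct_deaths_averted.
#' @export
adherence_grid <- function(bundle, config,
                           first_line = seq(0.2, 1, by = 0.2),
                           followup = c(0.6, 1),
                           strategies = c("FIT", "Colo")) {
  nh <- simulate_cohort(config, bundle$params, bundle$lifetable,
                        bundle$survival, tests = bundle$tests)
  ref_cases <- sum(!is.na(nh$persons$dx_age_months))
  ref_deaths <- sum(nh$persons$death_type == "crc")
  grid <- tidyr::expand_grid(strategy = strategies, adherence = first_line,
                             followup_adherence = followup)
  purrr::pmap(grid, function(strategy, adherence, followup_adherence) {
    s <- bundle$strategies[[strategy]]
    s$adherence <- adherence
    s$followup_adherence <- followup_adherence
    tr <- simulate_cohort(config, bundle$params, bundle$lifetable,
                          bundle$survival, strategy = s,
                          tests = bundle$tests)
    tibble::tibble(
      strategy = strategy, adherence = adherence,
      followup_adherence = followup_adherence,
      pct_cases_averted =
        (1 - sum(!is.na(tr$persons$dx_age_months)) / ref_cases) * 100,
      pct_deaths_averted =
        (1 - sum(tr$persons$death_type == "crc") / ref_deaths) * 100)
  }) |> dplyr::bind_rows()
}
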
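#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_effect` in USD per DALY averted. A zero effect
#' difference is undefined and returned as `NA` (never +/-Inf).
#'
#' @param delta_cost Incremental cost (USD, vectorised).
#' @param delta_effect Incremental effect (DALYs averted).
#' @return USD per DALY averted; `NA` where `delta_effect` is 0.
#' @examples
#' icer(27.50, 0.0129)
#' icer(70.04, 0.0054)
#' @export
icer <- function(delta_cost, delta_effect) {
  ifelse(delta_effect == 0, NA_real_, delta_cost / delta_effect)
}

#' Efficiency frontier and dominance analysis
#'
#' Sorts strategies by cost, removes strictly dominated strategies (at least
#' as costly and at most as effective as some other strategy, with one
#' relation strict), then iteratively removes extendedly dominated ones
#' (whose ICER against the previous frontier strategy exceeds the ICER of the
#' next), leaving strictly increasing frontier ICERs. The least costly
#' strategy is always on the frontier.
#'
#' @param outcomes Tibble with columns `strategy`, `cost`, `effect`
#'   (effect = DALYs averted vs the common reference; any common origin
#'   works). Duplicate names are an error; exact cost-and-effect duplicates
#'   are flagged in the output, not dropped.
#' @return A `crc_frontier`: the input with flags `strictly_dominated`,
#'   `extendedly_dominated`, `on_frontier`, `duplicate`, and `icer` (vs the
#'   previous frontier strategy; `NA` off-frontier and for the cheapest).
#' @export
find_frontier <- function(outcomes) {
  stopifnot(all(c("strategy", "cost", "effect") %in% names(outcomes)))
  if (anyDuplicated(outcomes$strategy) > 0) {
    stop("duplicate strategy names", call. = FALSE)
  }
  # ties in cost broken toward the more effective strategy
  out <- dplyr::arrange(tibble::as_tibble(outcomes), .data$cost,
                        dplyr::desc(.data$effect))
  n <- nrow(out)
  out$duplicate <- duplicated(out[, c("cost", "effect")]) |
    duplicated(out[, c("cost", "effect")], fromLast = TRUE)

  strict <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          out$cost[i] >= out$cost[j] && out$effect[i] <= out$effect[j] &&
          (out$cost[i] > out$cost[j] || out$effect[i] < out$effect[j])) {
        strict[i] <- TRUE
        break
      }
    }
  }
  out$strictly_dominated <- strict

  cand <- which(!strict)
  # iterative extended-dominance removal on the cost-ordered candidates
  repeat {
    if (length(cand) <= 2) break
    ic <- icer(diff(out$cost[cand]), diff(out$effect[cand]))
    drop <- which(diff(ic) < 0)  # ICER above the next one
    if (length(drop) == 0) break
    cand <- cand[-(drop[1] + 1L)]
  }
  out$extendedly_dominated <- !strict & !(seq_len(n) %in% cand)
  out$on_frontier <- seq_len(n) %in% cand
  out$icer <- NA_real_
  if (length(cand) > 1) {
    out$icer[cand[-1]] <- icer(diff(out$cost[cand]), diff(out$effect[cand]))
  }
  structure(out, class = c("crc_frontier", class(out)))
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' The most effective frontier strategy whose ICER against its frontier
#' predecessor does not exceed the threshold; the least costly strategy when
#' none qualifies. Monotone in the threshold.
#'
#' @param frontier A `crc_frontier` from [find_frontier()].
#' @param wtp Willingness to pay in USD per DALY averted (base 11,692,
#'   the Dominican Republic's 2024 GDP per capita).
#' @return The chosen strategy name.
#' @export
decide <- function(frontier, wtp = 11692) {
  stopifnot(wtp > 0, nrow(frontier) >= 1)
  on_f <- which(frontier$on_frontier)
  ok <- on_f[is.na(frontier$icer[on_f]) | frontier$icer[on_f] <= wtp]
  frontier$strategy[max(ok)]
}

#' Per-strategy outcome summary
#'
#' Fills one row of the cost-effectiveness table from a strategy trace and
#' the common-random-numbers reference (natural history): mean discounted
#' cost, mean DALYs averted versus the reference, average life expectancy,
#' CRC cases and deaths per 100,000 with percent averted, and lifetime
#' colonoscopies per 1,000.
#'
#' @param trace Strategy `crc_trace`.
#' @param costs Cost table.
#' @param weights Disability-weight table.
#' @param dsc A [discount_spec()].
#' @param reference Reference `crc_trace` (pass `trace` itself for the
#'   reference row).
#' @param name Strategy label; defaults to the trace's strategy name or "NH".
#' @param reference_dalys Optional precomputed [accrue_dalys()] result for
#'   the reference, to avoid recomputing it per strategy.
#' @return One-row tibble (a `StrategyOutcome`).
#' @export
summarize_strategy <- function(trace, costs, weights, dsc = discount_spec(),
                               reference = trace, name = NULL,
                               reference_dalys = NULL) {
  if (trace$config$n_persons != reference$config$n_persons) {
    stop("trace and reference have different cohort sizes", call. = FALSE)
  }
  n <- trace$config$n_persons
  if (is.null(name)) {
    name <- if (!is.null(trace$strategy)) trace$strategy$name else "NH"
  }
  cost <- accrue_costs(trace, costs, dsc)$mean
  if (is.null(reference_dalys)) {
    reference_dalys <- accrue_dalys(reference, weights, dsc)
  }
  own <- accrue_dalys(trace, weights, dsc)
  averted <- (own$mean_dly - reference_dalys$mean_dly) +
    (reference_dalys$mean_yld - own$mean_yld)
  life_exp <- trace$config$entry_age + mean(.months_alive(trace)) / 12

  cases <- sum(!is.na(trace$persons$dx_age_months)) / n
  deaths <- sum(trace$persons$death_type == "crc") / n
  ref_cases <- sum(!is.na(reference$persons$dx_age_months)) /
    reference$config$n_persons
  ref_deaths <- sum(reference$persons$death_type == "crc") /
    reference$config$n_persons

  endo <- count_endoscopies(trace)
  tibble::tibble(
    strategy = name,
    cost = cost,
    effect = averted,
    life_expectancy = life_exp,
    crc_cases_per_100k = cases * 1e5,
    crc_deaths_per_100k = deaths * 1e5,
    pct_cases_averted = if (ref_cases > 0) (1 - cases / ref_cases) * 100
                        else NA_real_,
    pct_deaths_averted = if (ref_deaths > 0) (1 - deaths / ref_deaths) * 100
                         else NA_real_,
    colonoscopies_per_1000 = endo$colonoscopies_per_1000,
    sigmoidoscopies_per_1000 = endo$sigmoidoscopies_per_1000)
}

#' Cost-effectiveness analysis over a set of strategy traces
#'
#' Summarises every trace against the natural-history reference, runs the
#' dominance/frontier analysis and the willingness-to-pay decision, and
#' reports incremental cost and incremental (frontier) DALYs averted
#' alongside the cumulative effect column.
#'
#' @param traces Named list of `crc_trace` objects; must include the
#'   reference.
#' @param reference_name Name of the reference (default `"NH"`).
#' @param costs,weights,dsc Economic inputs.
#' @param wtp Willingness-to-pay threshold.
#' @return A `crc_cea` list: `table` (per-strategy outcomes with dominance
#'   flags and ICERs), `frontier` (frontier strategy names in cost order),
#'   `optimal` (decision at `wtp`), `wtp`.
#' @export
cea_analysis <- function(traces, reference_name = "NH", costs, weights,
                         dsc = discount_spec(), wtp = 11692) {
  stopifnot(reference_name %in% names(traces))
  ref <- traces[[reference_name]]
  ref_dalys <- accrue_dalys(ref, weights, dsc)
  tab <- purrr::imap(traces, function(tr, nm) {
    summarize_strategy(tr, costs, weights, dsc, reference = ref, name = nm,
                       reference_dalys = ref_dalys)
  }) |> dplyr::bind_rows()

  fr <- find_frontier(tab[, c("strategy", "cost", "effect")])
  tab <- dplyr::left_join(
    tab,
    fr[, c("strategy", "strictly_dominated", "extendedly_dominated",
           "on_frontier", "icer")],
    by = "strategy") |>
    dplyr::arrange(.data$cost) |>
    dplyr::mutate(incremental_cost = .data$cost - dplyr::lag(.data$cost))

  structure(list(table = tab,
                 frontier = fr$strategy[fr$on_frontier],
                 optimal = decide(fr, wtp),
                 wtp = wtp),
            class = "crc_cea")
}

#' @export
print.crc_cea <- function(x, ...) {
  cat("<crc_cea> frontier: ", paste(x$frontier, collapse = " -> "),
      "; optimal at WTP ", format(x$wtp, big.mark = ","), ": ", x$optimal,
      "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.crc_cea <- function(x, ...) x$table

#' @export
glance.crc_cea <- function(x, ...) {
  tibble::tibble(n_strategies = nrow(x$table),
                 n_frontier = length(x$frontier),
                 optimal = x$optimal, wtp = x$wtp)
}

#' @export
tidy.crc_frontier <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.crc_calibration <- function(x, ...) x$best_params

#' @export
glance.crc_calibration <- function(x, ...) {
  tibble::tibble(best_objective = x$best_objective,
                 acceptance_rate = x$acceptance_rate,
                 iterations = nrow(x$trajectory))
}
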
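#' Currency conversion to 2024 US dollars
#'
#' Costs collected in Dominican pesos (DOP) are converted with a fixed
#' DOP-to-USD exchange rate (base 0.017) and a health-care CPI inflation
#' factor to 2024.
#'
#' @param rate DOP to USD exchange rate, default 0.017.
#' @param inflation Inflation factor to 2024 USD, default 1.
#' @return A `currency_spec` list.
#' @export
currency_spec <- function(rate = 0.017, inflation = 1) {
  stopifnot(rate > 0, inflation > 0)
  structure(list(rate = rate, inflation = inflation),
            class = "currency_spec")
}

#' @rdname currency_spec
#' @param amount_dop Amount in DOP (non-negative, vectorised).
#' @param spec A [currency_spec()].
#' @return Amount in 2024 USD.
#' @export
convert_currency <- function(amount_dop, spec = currency_spec()) {
  if (any(amount_dop < 0)) stop("`amount_dop` must be non-negative",
                                call. = FALSE)
  amount_dop * spec$rate * spec$inflation
}

#' Discounting settings
#'
#' @param rate Annual discount rate applied at monthly resolution
#'   (base 0.03); see [discount()].
#' @return A `discount_spec` list.
#' @export
discount_spec <- function(rate = 0.03) {
  stopifnot(rate >= 0)
  structure(list(rate = rate), class = "discount_spec")
}

# cost items the accrual understands
.COST_ITEMS <- c("colonoscopy", "sigmoidoscopy", "fit", "fobt",
                 "colonoscopy_followup", "colonoscopy_diagnostic",
                 "colonoscopy_surveillance", "complication",
                 "treatment_local", "treatment_regional", "treatment_distant")

#' Unit-cost table
#'
#' Long tibble with columns `item` and `cost` (2024 USD): one row per
#' screening test modality, per colonoscopy reason (follow-up, diagnostic,
#' surveillance — the bare `colonoscopy` item prices a primary screening
#' colonoscopy), a complication episode, and the stage-specific treatment
#' bundle charged once at diagnosis (surgery, hospitalization, imaging,
#' consultations and chemotherapy aggregated per stage).
#'
#' @param costs Tibble to validate.
#' @return The validated tibble.
#' @export
validate_cost_table <- function(costs) {
  stopifnot(all(c("item", "cost") %in% names(costs)))
  bad <- setdiff(costs$item, .COST_ITEMS)
  if (length(bad) > 0) {
    stop("unknown cost item(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(costs$cost < 0)) stop("costs must be non-negative", call. = FALSE)
  tibble::as_tibble(costs)
}

#' @rdname validate_cost_table
#' @param path CSV with columns `item, cost` and optionally `currency`
#'   (`"USD"` or `"DOP"`; DOP rows are converted on read).
#' @param currency A [currency_spec()] for DOP rows.
#' @export
read_cost_table <- function(path, currency = currency_spec()) {
  tb <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if ("currency" %in% names(tb)) {
    dop <- tb$currency == "DOP"
    tb$cost[dop] <- convert_currency(tb$cost[dop], currency)
    tb$currency <- NULL
  }
  validate_cost_table(tb)
}

#' @rdname validate_cost_table
#' @param x Cost table to write.
#' @export
write_cost_table <- function(x, path) {
  .write_table_csv(x, path)
}

#' Disability weights and episode durations
#'
#' Long tibble with columns `item`, `weight` and `duration_years`. Episode
#' items (`endoscopy`, `complication`, `treatment_local/regional/distant`)
#' accrue `weight x duration_years` at the event time. The
#' `cancer_local/regional/distant` items are living-with-cancer weights
#' (1 minus the stage utility) applied monthly for 120 months after
#' diagnosis or until death, whichever comes first; their `duration_years`
#' is ignored (`NA` by convention).
#'
#' @param weights Tibble to validate.
#' @return The validated tibble.
#' @export
validate_disability_weights <- function(weights) {
  stopifnot(all(c("item", "weight", "duration_years") %in% names(weights)))
  need <- c("endoscopy", "complication",
            paste0("treatment_", .STAGES), paste0("cancer_", .STAGES))
  missing <- setdiff(need, weights$item)
  if (length(missing) > 0) {
    stop("missing disability weight(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(weights$weight < 0 | weights$weight > 1)) {
    stop("disability weights must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(weights)
}

#' @rdname validate_disability_weights
#' @param path CSV with columns `item, weight, duration_years`.
#' @export
read_disability_weights <- function(path) {
  validate_disability_weights(
    readr::read_csv(path, show_col_types = FALSE, comment = "#"))
}

#' @rdname validate_disability_weights
#' @param x Weights table to write.
#' @export
write_disability_weights <- function(x, path) {
  .write_table_csv(x, path)
}

# map each costed event in a trace to a cost item
.event_cost_items <- function(events) {
  dplyr::case_when(
    events$event == "test_performed" &
      events$detail == "colonoscopy_screening" ~ "colonoscopy",
    events$event == "test_performed" &
      events$detail == "colonoscopy_followup" ~ "colonoscopy_followup",
    events$event == "test_performed" &
      events$detail == "colonoscopy_diagnostic" ~ "colonoscopy_diagnostic",
    events$event == "test_performed" &
      events$detail == "colonoscopy_surveillance" ~ "colonoscopy_surveillance",
    events$event == "test_performed" &
      startsWith(events$detail, "sigmoidoscopy") ~ "sigmoidoscopy",
    events$event == "test_performed" & startsWith(events$detail, "fit") ~ "fit",
    events$event == "test_performed" & startsWith(events$detail, "fobt") ~ "fobt",
    events$event == "complication" ~ "complication",
    events$event %in% c("symptomatic_dx", "screen_dx") ~
      paste0("treatment_", events$detail),
    TRUE ~ NA_character_
  )
}

#' Discounted per-person lifetime costs of a trace
#'
#' Every costed event is priced at its event month and discounted from model
#' start (age 20 is time 0). The stage-specific treatment bundle is charged
#' once, at diagnosis. Events without a price in the table raise a
#' configuration error naming the missing items.
#'
#' @param trace A `crc_trace`.
#' @param costs Cost table ([validate_cost_table()]).
#' @param dsc A [discount_spec()].
#' @return List: `per_person` (tibble `person`, `cost`, including zero-cost
#'   persons) and `mean` (the per-person lifetime cost).
#' @export
accrue_costs <- function(trace, costs, dsc = discount_spec()) {
  costs <- validate_cost_table(costs)
  ev <- trace$events
  item <- .event_cost_items(ev)
  keep <- !is.na(item)
  ev <- ev[keep, ]
  item <- item[keep]
  missing <- setdiff(unique(item), costs$item)
  if (length(missing) > 0) {
    stop("no price for event item(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  entry_m <- trace$config$entry_age * 12
  amt <- discount(costs$cost[match(item, costs$item)],
                  ev$age_months - entry_m, dsc$rate)
  total <- numeric(trace$config$n_persons)
  if (length(amt) > 0) {
    agg <- rowsum(amt, ev$person)
    total[as.integer(rownames(agg))] <- agg[, 1]
  }
  all_p <- tibble::tibble(person = seq_len(trace$config$n_persons),
                          cost = total)
  list(per_person = all_p, mean = mean(total))
}

# months lived in the model per person (full-cycle accrual: the death month
# counts as lived); horizon survivors live all cycles
.months_alive <- function(trace) {
  entry_m <- trace$config$entry_age * 12
  n_cycles <- (trace$config$horizon_age - trace$config$entry_age) * 12
  ifelse(is.na(trace$persons$death_age_months), n_cycles,
         trace$persons$death_age_months - entry_m + 1)
}

#' Discounted life-years and years lived with disability of a trace
#'
#' Discounted life-years (DLY) accrue 1/12 year per month alive. Years lived
#' with disability (YLD) accrue the living-with-cancer weight monthly for up
#' to 120 months after diagnosis (truncated at death), plus episode
#' disability (endoscopy, complication, stage-specific treatment period)
#' lumped at the event time. All accruals are discounted from model entry.
#'
#' @param trace A `crc_trace`.
#' @param weights Disability-weight table ([validate_disability_weights()]).
#' @param dsc A [discount_spec()].
#' @return List: `per_person` (tibble `person`, `dly`, `yld`), `mean_dly`,
#'   `mean_yld`.
#' @export
accrue_dalys <- function(trace, weights, dsc = discount_spec()) {
  weights <- validate_disability_weights(weights)
  w <- function(it) weights$weight[match(it, weights$item)]
  dur <- function(it) weights$duration_years[match(it, weights$item)]
  entry_m <- trace$config$entry_age * 12
  n <- trace$config$n_persons

  alive_m <- .months_alive(trace)
  dly <- .discounted_stream(1 / 12, 0, alive_m, dsc$rate)

  # living-with-cancer weight for <= 120 months post-diagnosis
  yld <- numeric(n)
  dxd <- !is.na(trace$persons$dx_age_months)
  if (any(dxd)) {
    m0 <- trace$persons$dx_age_months[dxd] - entry_m
    n_m <- pmin(120, alive_m[dxd] - m0)
    cw <- w(paste0("cancer_", trace$persons$dx_stage[dxd]))
    if (anyNA(cw)) stop("missing living-with-cancer weight", call. = FALSE)
    yld[dxd] <- .discounted_stream(cw / 12, m0, n_m, dsc$rate)
  }

  # episode disability lumped at the event month
  ev <- trace$events
  epi_item <- dplyr::case_when(
    ev$event == "test_performed" &
      (startsWith(ev$detail, "colonoscopy") |
         startsWith(ev$detail, "sigmoidoscopy")) ~ "endoscopy",
    ev$event == "complication" ~ "complication",
    ev$event %in% c("symptomatic_dx", "screen_dx") ~
      paste0("treatment_", ev$detail),
    TRUE ~ NA_character_)
  keep <- !is.na(epi_item)
  if (any(keep)) {
    amt <- discount(w(epi_item[keep]) * dur(epi_item[keep]),
                    ev$age_months[keep] - entry_m, dsc$rate)
    agg <- rowsum(amt, ev$person[keep])
    idx <- as.integer(rownames(agg))
    yld[idx] <- yld[idx] + agg[, 1]
  }

  per <- tibble::tibble(person = seq_len(n), dly = dly, yld = yld)
  list(per_person = per, mean_dly = mean(dly), mean_yld = mean(yld))
}

#' DALYs averted by a strategy relative to a reference trace
#'
#' Computed from the discounted life-year (DLY) and years-lived-with-
#' disability (YLD) identity: averted = (DLY_strategy - DLY_reference) +
#' (YLD_reference - YLD_strategy). Antisymmetric by construction.
#'
#' @param trace,reference `crc_trace` objects from identical configs.
#' @param weights Disability-weight table.
#' @param dsc A [discount_spec()].
#' @return Mean per-person DALYs averted (scalar).
#' @export
dalys_averted <- function(trace, reference, weights, dsc = discount_spec()) {
  if (trace$config$n_persons != reference$config$n_persons) {
    stop("traces have different cohort sizes", call. = FALSE)
  }
  a <- accrue_dalys(trace, weights, dsc)
  b <- accrue_dalys(reference, weights, dsc)
  (a$mean_dly - b$mean_dly) + (b$mean_yld - a$mean_yld)
}
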
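#' Cohort configuration
#'
#' @param n_persons Cohort size (base case 100,000).
#' @param entry_age Model entry age in years (20; the cohort enters free of
#'   adenomas).
#' @param horizon_age Horizon age in years (100; everyone alive at the horizon
#'   is censored there).
#' @param seed Master seed; every person's random stream is derived from it,
#'   so identical seeds reproduce identical traces and different strategy
#'   arms share common random numbers.
#' @return A `crc_cohort_config` list.
#' @export
cohort_config <- function(n_persons = 1e5, entry_age = 20, horizon_age = 100,
                          seed = 1L) {
  stopifnot(n_persons >= 1, entry_age < horizon_age)
  structure(list(n_persons = as.integer(n_persons),
                 entry_age = entry_age, horizon_age = horizon_age,
                 seed = as.double(seed)),
            class = "crc_cohort_config")
}

# default test characteristics used when a trace is run without a screening
# policy: only the colonoscopy complication probability is consulted (for the
# diagnostic colonoscopy at symptomatic presentation)
.default_test_chars_matrix <- function() {
  m <- matrix(0, 4, 7,
              dimnames = list(c("colonoscopy", "sigmoidoscopy", "fit", "fobt"),
                              c("sens_lr", "sens_hr", "sens_crc", "spec",
                                "compl", "whole_colon", "distal_fraction")))
  m[, "spec"] <- 1
  m[, "whole_colon"] <- 1
  m
}

.run_core <- function(config, params, lifetable, survival,
                      strategy = NULL, tests = NULL) {
  pmat <- .expand_params(params, config$entry_age, config$horizon_age)
  pdeath <- .expand_lifetable(lifetable, config$entry_age, config$horizon_age)
  .check_exit_probs(pmat, pdeath)
  pcancer <- .expand_stage_survival(survival)

  if (is.null(strategy)) {
    raw <- .sim_cohort_cpp(
      config$n_persons, config$seed, pmat, pdeath, pcancer,
      FALSE, integer(0), integer(0), integer(0), integer(0),
      0, 0, 0,
      if (is.null(tests)) .default_test_chars_matrix() else .test_chars_matrix(tests),
      36L, 60L, 0L, as.integer(config$entry_age * 12))
  } else {
    ph <- .strategy_phases(strategy)
    raw <- .sim_cohort_cpp(
      config$n_persons, config$seed, pmat, pdeath, pcancer,
      TRUE, ph$modality, ph$interval, ph$start, ph$stop,
      strategy$adherence, strategy$followup_adherence,
      strategy$surveillance_adherence,
      .test_chars_matrix(tests),
      as.integer(strategy$surveillance_intervals[1]),
      as.integer(strategy$surveillance_intervals[2]),
      as.integer(strategy$surveillance_stop_age * 12),
      as.integer(config$entry_age * 12))
  }
  .as_trace(raw, config, strategy)
}

.as_trace <- function(raw, config, strategy) {
  ev <- tibble::tibble(
    person = raw$person + 1L,
    age_months = raw$age_months,
    event = .EVENT_LEVELS[raw$event],
    detail = .decode_detail(.EVENT_LEVELS[raw$event], raw$detail))
  persons <- tibble::tibble(
    person = seq_len(config$n_persons),
    final_state = crc_states()[raw$final_state + 1L],
    death_age_months = ifelse(raw$death_age < 0, NA_integer_, raw$death_age),
    death_type = c("alive", "crc", "other")[raw$death_type + 1L],
    dx_age_months = ifelse(raw$dx_age < 0, NA_integer_, raw$dx_age),
    dx_stage = ifelse(raw$dx_stage < 0, NA_character_,
                      .STAGES[raw$dx_stage + 1L]))
  occ <- raw$occupancy
  colnames(occ) <- crc_states()
  structure(list(events = ev, persons = persons, occupancy = occ,
                 config = config, strategy = strategy),
            class = "crc_trace")
}

#' Simulate the natural-history (no-screening) disease process
#'
#' Runs the monthly-cycle microsimulation from entry (age 20, adenoma-free)
#' to age 100 or death. Each person-cycle makes a single multinomial draw over
#' the state's exit probabilities (disease transitions, all-cause death and —
#' for diagnosed persons within 10 years of diagnosis — stage-specific cancer
#' death), with the remainder a self-loop. Undetected (preclinical) cancer
#' carries no excess mortality; cancer-specific risk applies only after
#' diagnosis, for at most 120 months. A symptomatic diagnosis triggers one
#' diagnostic colonoscopy event.
#'
#' @param config A [cohort_config()].
#' @param params Natural-history parameter table (see [input-tables]).
#' @param lifetable Annual all-cause lifetable.
#' @param survival Stage-specific annual cancer mortality, years 1-10.
#' @param strategy Optional screening strategy ([strategy_spec()]); `NULL`
#'   simulates pure natural history.
#' @param tests Test-characteristics table ([test_characteristics()]);
#'   required when `strategy` is supplied.
#' @return A `crc_trace`: list with `events` (per-person event log),
#'   `persons` (per-person summary), `occupancy` (state counts by cycle),
#'   plus the configuration used.
#' @export
simulate_cohort <- function(config, params, lifetable, survival,
                            strategy = NULL, tests = NULL) {
  params <- validate_nh_params(params)
  lifetable <- validate_lifetable(lifetable)
  survival <- validate_stage_survival(survival)
  if (!is.null(strategy) && is.null(tests)) {
    stop("`tests` is required when simulating a screening strategy",
         call. = FALSE)
  }
  .run_core(config, params, lifetable, survival, strategy, tests)
}

#' @export
print.crc_trace <- function(x, ...) {
  cat("<crc_trace> ", x$config$n_persons, " persons, ",
      nrow(x$events), " events",
      if (!is.null(x$strategy)) paste0(", strategy ", x$strategy$name)
      else ", natural history", "\n", sep = "")
  invisible(x)
}

#' Occupancy of a trace as a tidy tibble
#'
#' @param trace A `crc_trace`.
#' @return Tibble with `cycle`, `state`, `count`, `fraction`.
#' @export
occupancy_tbl <- function(trace) {
  occ <- trace$occupancy
  tibble::tibble(
    cycle = rep(0:(nrow(occ) - 1), times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    count = as.vector(occ),
    fraction = as.vector(occ) / trace$config$n_persons)
}

#' Age-specific incidence, stage distribution and lifetime burden of a trace
#'
#' Incidence uses alive-and-undiagnosed person-time as the denominator.
#' Stage fractions are reported when at least one diagnosis occurred,
#' otherwise flagged as undefined.
#'
#' @param trace A `crc_trace`.
#' @param band_width Width of age bands in years for the incidence curve.
#' @return List with `incidence` (tibble: age_band_start, cases, person_years,
#'   rate_per_100k), `stage_distribution`, `lifetime` (case and CRC-death
#'   fractions) and `flagged` (TRUE when no diagnoses occurred).
#' @export
incidence_and_stage_summary <- function(trace, band_width = 5) {
  dx <- dplyr::filter(trace$events,
                      .data$event %in% c("symptomatic_dx", "screen_dx"))
  n <- trace$config$n_persons
  entry_m <- trace$config$entry_age * 12

  # alive-and-undiagnosed person-months by cycle from occupancy
  occ <- trace$occupancy
  at_risk <- rowSums(occ[, c("Healthy", "AdenomaLR", "AdenomaHR",
                             "PreclinLocal", "PreclinRegional",
                             "PreclinDistant")])
  cyc <- 0:(nrow(occ) - 1)
  age_years <- (entry_m + cyc) %/% 12
  band <- (age_years %/% band_width) * band_width
  py <- tibble::tibble(band = band[-length(band)],
                       pm = at_risk[-length(at_risk)]) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(person_years = sum(.data$pm) / 12, .groups = "drop")

  cases <- dx |>
    dplyr::mutate(band = ((.data$age_months %/% 12) %/% band_width) *
             band_width) |>
    dplyr::count(.data$band, name = "cases")

  incidence <- dplyr::left_join(py, cases, by = "band") |>
    dplyr::mutate(cases = dplyr::coalesce(.data$cases, 0L),
                  rate_per_100k = ifelse(.data$person_years > 0,
                                         .data$cases / .data$person_years * 1e5,
                                         0)) |>
    dplyr::rename(age_band_start = "band")

  flagged <- nrow(dx) == 0
  stage_distribution <- if (flagged) {
    tibble::tibble(stage = .STAGES, fraction = NA_real_)
  } else {
    dx |>
      dplyr::count(stage = factor(.data$detail, levels = .STAGES),
                   .drop = FALSE) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::select("stage", "fraction") |>
      dplyr::mutate(stage = as.character(.data$stage))
  }

  lifetime <- tibble::tibble(
    case_fraction = nrow(dx) / n,
    crc_death_fraction = sum(trace$persons$death_type == "crc") / n)

  list(incidence = incidence, stage_distribution = stage_distribution,
       lifetime = lifetime, flagged = flagged)
}
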
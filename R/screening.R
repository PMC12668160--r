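#' Screening test operating characteristics
#'
#' One row per modality: sensitivity by lesion class (low-risk adenoma,
#' high-risk adenoma, preclinical cancer), specificity, complication
#' probability per endoscopy, whether the test reaches the whole colon, and —
#' for distal-only endoscopy (sigmoidoscopy) — the fraction of lesions within
#' reach, which multiplies sensitivity. Stool tests must have complication
#' probability 0.
#'
#' @param modality One of `"colonoscopy"`, `"sigmoidoscopy"`, `"fit"`,
#'   `"fobt"` (vectorised).
#' @param sens_lr,sens_hr,sens_crc Sensitivities in \[0, 1\].
#' @param spec Specificity in \[0, 1\].
#' @param compl Complication probability per endoscopy.
#' @param whole_colon Logical; `FALSE` only for sigmoidoscopy.
#' @param distal_fraction Fraction of lesions within distal reach.
#' @return A `crc_tests` tibble.
#' @export
test_characteristics <- function(modality, sens_lr, sens_hr, sens_crc, spec,
                                 compl = 0, whole_colon = TRUE,
                                 distal_fraction = 1) {
  tb <- tibble::tibble(modality = modality, sens_lr = sens_lr,
                       sens_hr = sens_hr, sens_crc = sens_crc, spec = spec,
                       compl = compl, whole_colon = whole_colon,
                       distal_fraction = distal_fraction)
  validate_test_characteristics(tb)
}

#' @rdname test_characteristics
#' @param tests A test-characteristics tibble to validate.
#' @export
validate_test_characteristics <- function(tests) {
  stopifnot(all(c("modality", "sens_lr", "sens_hr", "sens_crc", "spec",
                  "compl") %in% names(tests)))
  bad <- setdiff(tests$modality, .MODALITIES)
  if (length(bad) > 0) {
    stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pr <- c(tests$sens_lr, tests$sens_hr, tests$sens_crc, tests$spec, tests$compl)
  if (any(!is.finite(pr) | pr < 0 | pr > 1)) {
    stop("test probabilities must lie in [0, 1]", call. = FALSE)
  }
  stool <- tests$modality %in% c("fit", "fobt")
  if (any(tests$compl[stool] != 0)) {
    stop("stool tests must have complication probability 0", call. = FALSE)
  }
  if (!"whole_colon" %in% names(tests)) tests$whole_colon <- TRUE
  if (!"distal_fraction" %in% names(tests)) tests$distal_fraction <- 1
  tibble::as_tibble(tests)
}

# 4 x 7 matrix in modality order colonoscopy/sigmoidoscopy/fit/fobt for the
# compiled core; missing modalities get inert defaults
.test_chars_matrix <- function(tests) {
  m <- .default_test_chars_matrix()
  for (k in seq_len(nrow(tests))) {
    row <- tests[k, ]
    m[row$modality, ] <- c(row$sens_lr, row$sens_hr, row$sens_crc, row$spec,
                           row$compl, as.numeric(row$whole_colon),
                           row$distal_fraction)
  }
  m
}

#' Screening strategy definition
#'
#' A policy is one or two phases of (modality, interval); the base-case
#' strategies are single-phase: colonoscopy every 10 years, sigmoidoscopy
#' every 5, FIT or FOBT every 2, all offered from age 45 through 75. The
#' two-phase form expresses the FIT-to-colonoscopy switch scenario.
#' First-line adherence is an independent Bernoulli draw per offer (base
#' 60.6\%); follow-up colonoscopy after a positive first-line test has its
#' own adherence (base 100\%). A negative colonoscopy — screening, follow-up
#' or surveillance — locks out further screening offers for 120 months.
#' Detected high-risk adenomas enter colonoscopy surveillance (first interval
#' 36 months, then 60 months) until the surveillance stop age (base 85).
#'
#' @param name Strategy label.
#' @param modality Modality of each phase.
#' @param interval_months Offer interval of each phase.
#' @param start_age,stop_age First-line screening ages in years
#'   (base 45-75). For two-phase strategies, vectors of length 2.
#' @param adherence First-line adherence probability (base 0.606).
#' @param followup_adherence Follow-up colonoscopy adherence (base 1).
#' @param surveillance_adherence Surveillance adherence (base 1).
#' @param surveillance_intervals Months to first and to subsequent
#'   surveillance colonoscopies (base `c(36, 60)`).
#' @param surveillance_stop_age Age in years at which surveillance ends
#'   (base 85).
#' @return A `crc_strategy` list.
#' @examples
#' strategy_spec("FIT", "fit", 24)
#' strategy_spec("FIT-Colo switch", c("fit", "colonoscopy"), c(24, 120),
#'               start_age = c(45, 50), stop_age = c(49, 75))
#' @export
strategy_spec <- function(name, modality, interval_months,
                          start_age = if (length(modality) == 1) 45 else c(45, 50),
                          stop_age = if (length(modality) == 1) 75 else c(49, 75),
                          adherence = 0.606, followup_adherence = 1,
                          surveillance_adherence = 1,
                          surveillance_intervals = c(36, 60),
                          surveillance_stop_age = 85) {
  stopifnot(length(modality) == length(interval_months),
            length(modality) == length(start_age),
            length(modality) == length(stop_age),
            all(modality %in% .MODALITIES),
            all(start_age < stop_age | stop_age == start_age),
            all(start_age <= stop_age),
            adherence >= 0, adherence <= 1,
            followup_adherence >= 0, followup_adherence <= 1,
            all(surveillance_intervals > 0))
  structure(list(name = name, modality = modality,
                 interval_months = as.integer(interval_months),
                 start_age = start_age, stop_age = stop_age,
                 adherence = adherence,
                 followup_adherence = followup_adherence,
                 surveillance_adherence = surveillance_adherence,
                 surveillance_intervals = surveillance_intervals,
                 surveillance_stop_age = surveillance_stop_age),
            class = "crc_strategy")
}

.strategy_phases <- function(strategy) {
  list(modality = as.integer(match(strategy$modality, .MODALITIES) - 1L),
       interval = as.integer(strategy$interval_months),
       start = as.integer(strategy$start_age * 12),
       stop = as.integer(strategy$stop_age * 12))
}

#' Base-case screening strategies
#'
#' Colonoscopy every 10 years, sigmoidoscopy every 5 years, biennial FIT and
#' biennial FOBT, all from age 45 to 75 with 60.6\% first-line adherence and
#' full follow-up adherence.
#'
#' @param adherence First-line adherence applied to all four strategies.
#' @param followup_adherence Follow-up colonoscopy adherence.
#' @param start_age,stop_age Screening window in years.
#' @param surveillance_stop_age Surveillance stop age in years.
#' @return Named list of [strategy_spec()] objects.
#' @export
base_strategies <- function(adherence = 0.606, followup_adherence = 1,
                            start_age = 45, stop_age = 75,
                            surveillance_stop_age = 85) {
  mk <- function(name, modality, interval) {
    strategy_spec(name, modality, interval, start_age = start_age,
                  stop_age = stop_age, adherence = adherence,
                  followup_adherence = followup_adherence,
                  surveillance_stop_age = surveillance_stop_age)
  }
  list(Colo = mk("Colo", "colonoscopy", 120),
       Sig  = mk("Sig", "sigmoidoscopy", 60),
       FIT  = mk("FIT", "fit", 24),
       FOBT = mk("FOBT", "fobt", 24))
}

#' Overlay a screening strategy on the natural-history simulation
#'
#' Identical to [simulate_cohort()] with a strategy: offers are made on the
#' strategy's age grid, adherence is drawn per offer, positive stool or
#' sigmoidoscopy results trigger a follow-up colonoscopy, detected adenomas
#' are completely removed (high-risk removal enrolls surveillance), detected
#' preclinical cancer becomes clinical at the same stage, and negative
#' colonoscopies impose the 120-month lockout. Disease-transition draws share
#' the natural-history arm's random numbers, so a policy that never touches
#' anyone (adherence 0) reproduces the natural-history trace exactly.
#'
#' @inheritParams simulate_cohort
#' @param strategy A [strategy_spec()].
#' @param tests Test characteristics covering the strategy's modalities and
#'   colonoscopy.
#' @return A `crc_trace` with screening events.
#' @export
run_strategy <- function(config, params, lifetable, survival, strategy, tests) {
  simulate_cohort(config, params, lifetable, survival,
                  strategy = strategy, tests = tests)
}

#' Count colonoscopies and sigmoidoscopies in a trace
#'
#' Colonoscopies of every reason (screening, follow-up, surveillance,
#' diagnostic) count together; sigmoidoscopies are tallied separately.
#'
#' @param trace A `crc_trace`.
#' @return Tibble with `colonoscopies`, `sigmoidoscopies`, and per-1,000
#'   rates.
#' @export
count_endoscopies <- function(trace) {
  tests <- dplyr::filter(trace$events, .data$event == "test_performed")
  n <- trace$config$n_persons
  colo <- sum(startsWith(tests$detail, "colonoscopy"))
  sig <- sum(startsWith(tests$detail, "sigmoidoscopy"))
  tibble::tibble(colonoscopies = colo, sigmoidoscopies = sig,
                 colonoscopies_per_1000 = colo / n * 1000,
                 sigmoidoscopies_per_1000 = sig / n * 1000)
}
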
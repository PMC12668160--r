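# run code under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# multiplicative jitter, symmetric on the log scale
.jitter <- function(x, frac) x * exp(stats::runif(length(x), -frac, frac))

# fixture values are rounded to 7 significant digits so every file written
# by the bundle writers re-reads to the identical double (short decimals
# round-trip exactly through the CSV layer)
.sig <- function(x) signif(x, 7)

#' Synthetic all-cause lifetable
#'
#' Gompertz-Makeham-shaped annual death probabilities
#' `qx = 1 - exp(-(a + b e^(c age)))` for ages 0-100, with a small seeded
#' jitter on the level. The `"mid"` level emulates a middle-income-country
#' lifetable (life expectancy at age 20 between 50 and 65 years); `"low"` and
#' `"high"` shift overall mortality down or up; `"zero"` returns an all-zero
#' table for conservation tests.
#'
#' @param level `"low"`, `"mid"`, `"high"` or `"zero"`.
#' @param seed Seed for the jitter.
#' @return Lifetable tibble (`age`, `qx`).
#' @export
make_lifetable <- function(level = c("mid", "low", "high", "zero"), seed = 1L) {
  level <- match.arg(level)
  ages <- 0:100
  if (level == "zero") return(tibble::tibble(age = ages, qx = 0))
  mult <- switch(level, low = 0.6, mid = 1, high = 1.6)
  .with_seed(seed, {
    a <- 0.0008 * mult * exp(stats::runif(1, -0.05, 0.05))
    b <- 3.2e-05 * mult * exp(stats::runif(1, -0.05, 0.05))
    cc <- 0.093
    hazard <- a + b * exp(cc * ages)
    tibble::tibble(age = ages, qx = .sig(pmin(1 - exp(-hazard), 1)))
  })
}

#' Synthetic stage-specific cancer survival
#'
#' Annual cancer-specific death probabilities for 10 post-diagnosis years,
#' highest in year 1 and declining geometrically, with distant >= regional >=
#' local at every year by construction.
#'
#' @param seed Seed for the jitter.
#' @return Stage-survival tibble (`stage`, `year`, `qx_cancer`).
#' @export
make_stage_survival <- function(seed = 1L) {
  .with_seed(seed, {
    base1 <- c(local = 0.030, regional = 0.110, distant = 0.420) *
      exp(stats::runif(3, -0.05, 0.05))
    base1 <- sort(base1)  # guard the ordering under jitter
    base1 <- stats::setNames(base1, c("local", "regional", "distant"))
    decline <- c(local = 0.85, regional = 0.82, distant = 0.80)
    purrr::map(names(base1), function(s) {
      tibble::tibble(stage = s, year = 1:10,
                     qx_cancer = .sig(base1[[s]] * decline[[s]]^(0:9)))
    }) |>
      dplyr::bind_rows() |>
      validate_stage_survival()
  })
}

# Base truth values per variant, chosen so the stated envelopes hold for any
# jitter seed and so every parameter is identifiable from the target classes
# the calibration consumes. Sojourn scales are deliberately long (years, not
# months): with fast transit the targets pin only the ratios of the
# preclinical rates, because internal timing shorter than the age resolution
# leaves no signature; at these scales every rate competes visibly with
# all-cause mortality (the "leak" of undetected cancer into other-cause
# death), giving each a first-order fingerprint in incidence level, timing
# and stage mix. The two adenoma-progression rates are set equal: a series of
# two first-order transitions is observationally symmetric in its rates, so
# only the unordered pair is identified; at the symmetric point that pair
# determines both values.
.truth_base <- function(variant) {
  onset <- tibble::tibble(
    age_band_start = c(20, 40, 50, 60, 70),
    age_band_end = c(40, 50, 60, 70, 100),
    monthly_probability = c(2.2e-4, 6.6e-4, 1.1e-3, 1.55e-3, 1.75e-3))
  if (variant == "DR-like") {
    list(adenoma_onset = onset, adenoma_progression = 1.6e-3,
         local_to_regional = 0.010, regional_to_distant = 0.016,
         detect_local = 0.004, detect_regional = 0.012,
         detect_distant = 0.022)
  } else {
    list(adenoma_onset = onset, adenoma_progression = 1.6e-3,
         local_to_regional = 0.008, regional_to_distant = 0.016,
         detect_local = 0.010, detect_regional = 0.018,
         detect_distant = 0.024)
  }
}

#' Synthetic "true" natural-history parameters and matching targets
#'
#' Draws a truth parameter set around variant-specific base values (small
#' seeded log-scale jitter) and derives calibration targets from the truth
#' itself via the deterministic forward operator, so the calibration
#' objective at the truth is exactly zero. The `"DR-like"` variant has a
#' late-stage-skewed mix at diagnosis (majority regional+distant, emulating
#' referral-hospital stage data from a country without screening); the
#' `"SEER8-like"` variant detects earlier (majority local+regional, emulating
#' pre-screening-era US registry data).
#'
#' @param variant `"DR-like"` or `"SEER8-like"`.
#' @param seed Seed for the truth jitter.
#' @param lifetable Lifetable the targets are computed under; defaults to
#'   `make_lifetable("mid", seed)`.
#' @return List: `truth` (parameter table), `targets` (target tibble).
#' @export
make_truth_and_targets <- function(variant = c("DR-like", "SEER8-like"),
                                   seed = 1L, lifetable = NULL) {
  variant <- match.arg(variant)
  if (is.null(lifetable)) lifetable <- make_lifetable("mid", seed)
  base <- .truth_base(variant)
  truth <- .with_seed(seed + 1000L, {
    vals <- purrr::imap(base, function(v, nm) {
      if (is.numeric(v)) .jitter(v, 0.08)
      else dplyr::mutate(v, monthly_probability =
                              .jitter(.data$monthly_probability, 0.08))
    })
    # the shared progression rate feeds both adenoma transitions
    vals$lr_to_hr <- vals$adenoma_progression
    vals$hr_to_preclin <- vals$adenoma_progression
    vals$adenoma_progression <- NULL
    p <- nh_params(vals)
    p$monthly_probability <- .sig(p$monthly_probability)
    p
  })
  # single-year incidence targets: the timing signatures that identify the
  # preclinical sojourn parameters live at the one-to-two-year scale, which
  # five-year bands average away (registry rates are published at this
  # resolution too)
  fw <- forward_targets(truth, lifetable, band_width = 1,
                        prevalence_ages = c(40, 50, 60, 70, 80))
  inc <- dplyr::filter(fw$incidence, .data$age_band_start >= 40,
                       .data$age_band_start <= 90)
  targets <- dplyr::bind_rows(
    tibble::tibble(target_class = "incidence",
                   key = as.character(inc$age_band_start),
                   value = .sig(inc$rate_per_100k), weight = 1),
    tibble::tibble(target_class = "prevalence",
                   key = as.character(fw$prevalence$age),
                   value = .sig(fw$prevalence$prevalence), weight = 1),
    # the three stage fractions carry most of the information on the
    # detection-versus-progression balance; their weight offsets their
    # small number relative to the incidence and prevalence rows
    tibble::tibble(target_class = "stage",
                   key = fw$stage_distribution$stage,
                   value = fw$stage_distribution$fraction, weight = 10))
  # keep the stage simplex summing to exactly 1 after rounding
  stg <- targets$target_class == "stage"
  v <- .sig(targets$value[stg])
  v[3] <- 1 - v[1] - v[2]
  targets$value[stg] <- v
  list(truth = truth, targets = validate_targets(targets))
}

#' Complete synthetic fixture bundle
#'
#' Generates every input the pipeline needs: lifetable, stage survival, truth
#' parameters with calibration targets derived from them, unit costs, test
#' operating characteristics for the four modalities, disability weights, and
#' the four base-case strategies. All values are documented placeholders with
#' the field's ordinal structure (stool test < sigmoidoscopy < colonoscopy <
#' treatment costs; distant >= regional >= local treatment cost and
#' disability; colonoscopy >= sigmoidoscopy >= FIT >= FOBT sensitivity per
#' lesion class; FIT specificity >= FOBT), never estimates of any real
#' price list or registry.
#'
#' @inheritParams make_truth_and_targets
#' @return A `crc_bundle` list: `variant`, `seed`, `lifetable`, `survival`,
#'   `params` (the truth), `targets`, `costs`, `tests`, `weights`,
#'   `strategies`, `notes`.
#' @export
make_fixture_bundle <- function(variant = c("DR-like", "SEER8-like"),
                                seed = 1L) {
  variant <- match.arg(variant)
  lifetable <- make_lifetable("mid", seed)
  survival <- make_stage_survival(seed)
  tt <- make_truth_and_targets(variant, seed, lifetable)

  costs <- .with_seed(seed + 2000L, {
    tibble::tibble(
      item = .COST_ITEMS,
      cost = .sig(c(130, 45, 6, 4, 130, 130, 130, 550, 2800, 5600, 8400) *
                    exp(stats::runif(11, -0.05, 0.05))))
  })

  tests <- .with_seed(seed + 3000L, {
    j <- function(x) .sig(pmin(.jitter(x, 0.02), 1))
    validate_test_characteristics(tibble::tibble(
      modality = c("colonoscopy", "sigmoidoscopy", "fit", "fobt"),
      sens_lr = j(c(0.75, 0.70, 0.10, 0.05)),
      sens_hr = j(c(0.95, 0.90, 0.25, 0.15)),
      sens_crc = j(c(0.95, 0.90, 0.75, 0.50)),
      spec = c(1, j(c(0.92, 0.96, 0.90))),
      compl = c(0.002, 0.0005, 0, 0),
      whole_colon = c(TRUE, FALSE, TRUE, TRUE),
      distal_fraction = c(1, 0.6, 1, 1)))
  })

  weights <- tibble::tibble(
    item = c("endoscopy", "complication",
             paste0("treatment_", .STAGES), paste0("cancer_", .STAGES)),
    weight = c(0.09, 0.324, 0.288, 0.288, 0.451, 0.13, 0.24, 0.38),
    duration_years = .sig(c(2 / 365.25, 14 / 365.25, 0.25, 0.5, 2 / 3,
                            NA, NA, NA)))

  notes <- tibble::tibble(
    component = c("lifetable", "stage_survival", "nh_params", "targets",
                  "costs", "tests", "weights", "strategies"),
    status = c("placeholder", "placeholder", "placeholder", "derived",
               "placeholder", "placeholder", "placeholder", "placeholder"),
    note = c(
      "Gompertz-Makeham shape, middle-income-country level",
      "geometric decline over 10 post-diagnosis years, ordered by stage",
      "synthetic truth; ordinal structure only, no registry estimate",
      "computed from the truth parameters via the deterministic oracle",
      "ordered placeholder magnitudes in 2024 USD",
      "ordered placeholder operating characteristics",
      "placeholder weights and episode durations",
      "base-case policies: Colo 10y, Sig 5y, FIT 2y, FOBT 2y, ages 45-75"))

  structure(list(variant = variant, seed = as.integer(seed),
                 lifetable = lifetable, survival = survival,
                 params = tt$truth, targets = tt$targets, costs = costs,
                 tests = tests, weights = weights,
                 strategies = base_strategies(), notes = notes),
            class = "crc_bundle")
}

#' @export
print.crc_bundle <- function(x, ...) {
  cat("<crc_bundle> variant ", x$variant, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write or read a fixture bundle as a directory of CSV files
#'
#' Every table lands in one CSV (`lifetable.csv`, `stage_survival.csv`,
#' `nh_params.csv`, `targets.csv`, `costs.csv`, `tests.csv`, `weights.csv`,
#' `strategies.csv`, `notes.csv`) plus `meta.yaml` with the variant and seed.
#'
#' @param bundle A `crc_bundle`.
#' @param dir Directory to write into (created if missing).
#' @return `write_fixture_bundle`: `dir`, invisibly; `read_fixture_bundle`:
#'   the bundle.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_lifetable(bundle$lifetable, file.path(dir, "lifetable.csv"))
  write_stage_survival(bundle$survival, file.path(dir, "stage_survival.csv"))
  write_nh_params(bundle$params, file.path(dir, "nh_params.csv"))
  write_targets(bundle$targets, file.path(dir, "targets.csv"))
  write_cost_table(bundle$costs, file.path(dir, "costs.csv"))
  .write_table_csv(bundle$tests, file.path(dir, "tests.csv"))
  write_disability_weights(bundle$weights, file.path(dir, "weights.csv"))
  strat <- purrr::imap(bundle$strategies, function(s, nm) {
    tibble::tibble(name = nm, phase = seq_along(s$modality),
                   modality = s$modality,
                   interval_months = s$interval_months,
                   start_age = s$start_age, stop_age = s$stop_age,
                   adherence = s$adherence,
                   followup_adherence = s$followup_adherence,
                   surveillance_adherence = s$surveillance_adherence,
                   surveillance_first = s$surveillance_intervals[1],
                   surveillance_later = s$surveillance_intervals[2],
                   surveillance_stop_age = s$surveillance_stop_age)
  }) |> dplyr::bind_rows()
  .write_table_csv(strat, file.path(dir, "strategies.csv"))
  readr::write_csv(bundle$notes, file.path(dir, "notes.csv"))
  yaml::write_yaml(list(variant = bundle$variant, seed = bundle$seed),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  strat <- readr::read_csv(file.path(dir, "strategies.csv"),
                           show_col_types = FALSE)
  strategies <- purrr::map(split(strat, factor(strat$name,
                                               levels = unique(strat$name))),
                           function(g) {
    g <- dplyr::arrange(g, .data$phase)
    strategy_spec(g$name[1], g$modality, g$interval_months,
                  start_age = g$start_age, stop_age = g$stop_age,
                  adherence = g$adherence[1],
                  followup_adherence = g$followup_adherence[1],
                  surveillance_adherence = g$surveillance_adherence[1],
                  surveillance_intervals = c(g$surveillance_first[1],
                                             g$surveillance_later[1]),
                  surveillance_stop_age = g$surveillance_stop_age[1])
  })
  structure(list(
    variant = meta$variant, seed = meta$seed,
    lifetable = read_lifetable(file.path(dir, "lifetable.csv")),
    survival = read_stage_survival(file.path(dir, "stage_survival.csv")),
    params = read_nh_params(file.path(dir, "nh_params.csv")),
    targets = read_targets(file.path(dir, "targets.csv")),
    costs = read_cost_table(file.path(dir, "costs.csv")),
    tests = validate_test_characteristics(
      readr::read_csv(file.path(dir, "tests.csv"), show_col_types = FALSE)),
    weights = read_disability_weights(file.path(dir, "weights.csv")),
    strategies = strategies,
    notes = readr::read_csv(file.path(dir, "notes.csv"),
                            show_col_types = FALSE)),
    class = "crc_bundle")
}
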
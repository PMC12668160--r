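#' Run configuration
#'
#' The pipeline is driven by one structured YAML file with nested blocks:
#'
#' ```yaml
#' output_dir: runs/base
#' fixtures: {dir: runs/base/fixtures, variant: DR-like, seed: 1}
#' cohort: {n_persons: 20000, seed: 42}
#' economics: {discount_rate: 0.03, wtp: 11692}
#' calibration: {max_iter: 3000, seed: 7, step: 0.1}
#' psa: {n_iter: 200, seed: 11}
#' ```
#'
#' `read_run_config()` parses the file; [validate_config()] checks every
#' declared invariant and returns violations instead of erroring, so a
#' front-end can show them all at once.
#'
#' @param path YAML file path.
#' @return Named list (the config), with a `config_hash` attribute.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  attr(cfg, "config_hash") <- rlang::hash(cfg)
  cfg
}

.default_config <- function() {
  list(output_dir = "run",
       fixtures = list(dir = NULL, variant = "DR-like", seed = 1L),
       cohort = list(n_persons = 20000L, seed = 42L),
       economics = list(discount_rate = 0.03, wtp = 11692),
       calibration = list(max_iter = 3000L, seed = 7L, step = 0.1),
       psa = list(n_iter = 200L, seed = 11L),
       adherence = NULL, followup_adherence = NULL,
       start_age = NULL, stop_age = NULL)
}

# fill defaults for missing keys (one level of nesting)
.fill_config <- function(config) {
  def <- .default_config()
  for (k in names(def)) {
    if (is.null(config[[k]])) {
      config[[k]] <- def[[k]]
    } else if (is.list(def[[k]])) {
      for (kk in names(def[[k]])) {
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- def[[k]][[kk]]
      }
    }
  }
  if (is.null(config$fixtures$dir)) {
    config$fixtures$dir <- file.path(config$output_dir, "fixtures")
  }
  if (is.null(attr(config, "config_hash"))) {
    attr(config, "config_hash") <- rlang::hash(config)
  }
  config
}

#' Validate a run configuration
#'
#' Checks the type invariants the pipeline relies on (known keys,
#' probabilities in range, screening start before stop, positive cohort and
#' iteration counts) and returns all violations.
#'
#' @param config Config list from [read_run_config()] or built in code.
#' @return Character vector of violations; `character(0)` when the config is
#'   valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  known <- c(names(.default_config()), "scenarios", "dsa")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    v <- c(v, paste0("unknown config key(s): ",
                     paste(unknown, collapse = ", ")))
  }
  config <- .fill_config(config)
  chk01 <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || x < 0 || x > 1))
      paste0(nm, " must lie in [0, 1]") else character(0)
  }
  v <- c(v, chk01(config$adherence, "adherence"),
         chk01(config$followup_adherence, "followup_adherence"))
  if (!is.null(config$start_age) && !is.null(config$stop_age) &&
      config$start_age >= config$stop_age) {
    v <- c(v, paste0("start_age (", config$start_age,
                     ") must be below stop_age (", config$stop_age, ")"))
  }
  if (config$cohort$n_persons < 1) v <- c(v, "cohort n_persons must be >= 1")
  if (config$economics$discount_rate < 0) {
    v <- c(v, "economics discount_rate must be >= 0")
  }
  if (config$economics$wtp <= 0) v <- c(v, "economics wtp must be positive")
  if (!config$fixtures$variant %in% c("DR-like", "SEER8-like")) {
    v <- c(v, "fixtures variant must be 'DR-like' or 'SEER8-like'")
  }
  if (config$psa$n_iter < 1) v <- c(v, "psa n_iter must be >= 1")
  v
}

.stamp <- function(config) {
  paste0("# config ", attr(config, "config_hash"),
         " cohort_seed ", config$cohort$seed)
}

# write a CSV with a provenance header comment (readers skip '#' lines)
.write_output <- function(x, path, config) {
  writeLines(.stamp(config), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.need_upstream <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing ", basename(path), "; run the '", producer,
         "' command first", call. = FALSE)
  }
  path
}

#' Pipeline commands
#'
#' Each command reads and writes only documented files under the config's
#' `output_dir`:
#'
#' * `cmd_fixtures()` generates the synthetic fixture bundle directory.
#' * `cmd_calibrate()` anneals from a perturbed start against the bundle's
#'   targets and writes `calibrated_params.csv` + `calibration_meta.yaml`.
#' * `cmd_simulate()` runs natural history and the four strategies with the
#'   calibrated (or truth) parameters and writes `outcomes.csv`.
#' * `cmd_cea()` reads `outcomes.csv`, runs the frontier/decision logic and
#'   writes `cea_table.csv` + `decision.yaml`.
#' * `cmd_report()` assembles `report.md` from the stored outputs without
#'   recomputing anything.
#'
#' `run_pipeline()` chains fixtures, simulate, cea and report (calibration is
#' opt-in via `calibrate = TRUE` since the bundle ships truth parameters).
#'
#' @param config Run configuration (see [read_run_config()]); validated
#'   before any computation.
#' @return Each command returns its main output path, invisibly;
#'   `run_pipeline()` returns the `crc_cea` of the base analysis.
#' @name pipeline
NULL

.check_config <- function(config) {
  v <- validate_config(config)
  if (length(v) > 0) {
    stop("invalid config:\n", paste0("  - ", v, collapse = "\n"),
         call. = FALSE)
  }
  .fill_config(config)
}

#' @rdname pipeline
#' @export
cmd_fixtures <- function(config) {
  config <- .check_config(config)
  bundle <- make_fixture_bundle(config$fixtures$variant,
                                config$fixtures$seed)
  write_fixture_bundle(bundle, config$fixtures$dir)
  invisible(config$fixtures$dir)
}

#' @rdname pipeline
#' @export
cmd_calibrate <- function(config) {
  config <- .check_config(config)
  dir <- config$fixtures$dir
  .need_upstream(file.path(dir, "targets.csv"), "fixtures")
  bundle <- read_fixture_bundle(dir)
  start <- .with_seed(config$calibration$seed, {
    p <- bundle$params
    p$monthly_probability <- p$monthly_probability *
      stats::runif(nrow(p), 0.5, 2)
    p
  })
  fit <- anneal(bundle$targets,
                anneal_schedule(max_iter = config$calibration$max_iter,
                                step = config$calibration$step,
                                seed = config$calibration$seed),
                start, lifetable = bundle$lifetable)
  out <- file.path(config$output_dir, "calibrated_params.csv")
  if (!dir.exists(config$output_dir)) dir.create(config$output_dir,
                                                 recursive = TRUE)
  write_nh_params(fit$best_params, out)
  yaml::write_yaml(list(seed = config$calibration$seed,
                        max_iter = config$calibration$max_iter,
                        best_objective = fit$best_objective,
                        acceptance_rate = fit$acceptance_rate),
                   file.path(config$output_dir, "calibration_meta.yaml"))
  readr::write_csv(fit$trajectory,
                   file.path(config$output_dir, "calibration_trajectory.csv"))
  invisible(out)
}

# assemble bundle + any config-level strategy overrides
.configured_bundle <- function(config) {
  bundle <- read_fixture_bundle(config$fixtures$dir)
  calib <- file.path(config$output_dir, "calibrated_params.csv")
  if (file.exists(calib)) bundle$params <- read_nh_params(calib)
  bundle$strategies <- lapply(bundle$strategies, function(s) {
    if (!is.null(config$adherence)) s$adherence <- config$adherence
    if (!is.null(config$followup_adherence))
      s$followup_adherence <- config$followup_adherence
    if (!is.null(config$start_age)) s$start_age[1] <- config$start_age
    if (!is.null(config$stop_age))
      s$stop_age[length(s$stop_age)] <- config$stop_age
    s
  })
  bundle
}

#' @rdname pipeline
#' @export
cmd_simulate <- function(config) {
  config <- .check_config(config)
  .need_upstream(file.path(config$fixtures$dir, "nh_params.csv"), "fixtures")
  bundle <- .configured_bundle(config)
  cfg <- cohort_config(config$cohort$n_persons, seed = config$cohort$seed)
  dsc <- discount_spec(config$economics$discount_rate)
  cea <- .evaluate_bundle(bundle, cfg, dsc = dsc, wtp = config$economics$wtp)
  if (!dir.exists(config$output_dir)) dir.create(config$output_dir,
                                                 recursive = TRUE)
  out <- file.path(config$output_dir, "outcomes.csv")
  .write_output(cea$table[, c("strategy", "cost", "effect",
                              "life_expectancy", "crc_cases_per_100k",
                              "crc_deaths_per_100k", "pct_cases_averted",
                              "pct_deaths_averted",
                              "colonoscopies_per_1000")],
                out, config)
  invisible(out)
}

#' @rdname pipeline
#' @export
cmd_cea <- function(config) {
  config <- .check_config(config)
  path <- file.path(config$output_dir, "outcomes.csv")
  .need_upstream(path, "simulate")
  outcomes <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  fr <- find_frontier(outcomes[, c("strategy", "cost", "effect")])
  tab <- dplyr::left_join(
    outcomes,
    fr[, c("strategy", "strictly_dominated", "extendedly_dominated",
           "on_frontier", "icer")],
    by = "strategy") |> dplyr::arrange(.data$cost)
  out <- file.path(config$output_dir, "cea_table.csv")
  .write_output(tab, out, config)
  yaml::write_yaml(
    list(frontier = as.list(fr$strategy[fr$on_frontier]),
         optimal = decide(fr, config$economics$wtp),
         wtp = config$economics$wtp),
    file.path(config$output_dir, "decision.yaml"))
  invisible(out)
}

#' @rdname pipeline
#' @export
cmd_report <- function(config) {
  config <- .check_config(config)
  cea_path <- .need_upstream(file.path(config$output_dir, "cea_table.csv"),
                             "cea")
  dec <- yaml::read_yaml(file.path(config$output_dir, "decision.yaml"))
  tab_lines <- readLines(cea_path)
  out <- file.path(config$output_dir, "report.md")
  writeLines(c(
    "# Screening cost-effectiveness run report",
    "",
    paste0("Frontier: ", paste(unlist(dec$frontier), collapse = " -> ")),
    paste0("Optimal at WTP ", dec$wtp, ": ", dec$optimal),
    "",
    "## CEA table (verbatim from cea_table.csv)",
    "```",
    tab_lines,
    "```"), out)
  invisible(out)
}

#' @rdname pipeline
#' @param calibrate Run the annealing stage instead of using the bundle's
#'   truth parameters.
#' @export
run_pipeline <- function(config, calibrate = FALSE) {
  config <- .check_config(config)
  cmd_fixtures(config)
  if (calibrate) cmd_calibrate(config)
  cmd_simulate(config)
  cmd_cea(config)
  cmd_report(config)
  outcomes <- readr::read_csv(file.path(config$output_dir, "outcomes.csv"),
                              show_col_types = FALSE, comment = "#")
  fr <- find_frontier(outcomes[, c("strategy", "cost", "effect")])
  structure(list(table = outcomes, frontier = fr$strategy[fr$on_frontier],
                 optimal = decide(fr, config$economics$wtp),
                 wtp = config$economics$wtp),
            class = "crc_cea")
}
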
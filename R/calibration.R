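#' Calibration targets
#'
#' Targets are a long tibble with columns `target_class` (`"incidence"`,
#' `"prevalence"`, `"stage"`), `key` (age-band start for incidence, age for
#' prevalence, stage name for stage), `value` and `weight`. Incidence values
#' are cases per 100,000 alive-and-undiagnosed person-years, prevalence values
#' are fractions of alive undiagnosed persons with any adenoma, and the three
#' stage values are the stage distribution at diagnosis (summing to 1).
#'
#' @param targets Tibble to validate.
#' @return The validated tibble.
#' @export
validate_targets <- function(targets) {
  stopifnot(all(c("target_class", "key", "value", "weight") %in% names(targets)))
  bad <- setdiff(unique(targets$target_class),
                 c("incidence", "prevalence", "stage"))
  if (length(bad) > 0) {
    stop("unknown target class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(targets$value) | targets$value < 0)) {
    stop("target values must be finite and non-negative", call. = FALSE)
  }
  stg <- dplyr::filter(targets, .data$target_class == "stage")
  if (nrow(stg) > 0 && abs(sum(stg$value) - 1) > 1e-9) {
    stop("stage-distribution target must sum to 1", call. = FALSE)
  }
  tibble::as_tibble(targets)
}

#' @rdname validate_targets
#' @param path CSV file with columns `target_class, key, value, weight`.
#' @export
read_targets <- function(path) {
  validate_targets(readr::read_csv(path, show_col_types = FALSE,
                                   comment = "#"))
}

#' @rdname validate_targets
#' @param x Targets tibble to write.
#' @export
write_targets <- function(x, path) {
  .write_table_csv(x, path)
}

# incidence band width implied by the spacing of the incidence target keys
.infer_band_width <- function(targets, default = 5) {
  keys <- suppressWarnings(as.numeric(
    targets$key[targets$target_class == "incidence"]))
  keys <- sort(unique(keys[is.finite(keys)]))
  if (length(keys) >= 2) min(diff(keys)) else default
}

# model values for each target row, from the deterministic forward operator
.model_values <- function(params, targets, lifetable,
                          entry_age = 20, horizon_age = 100,
                          band_width = NULL) {
  if (is.null(band_width)) band_width <- .infer_band_width(targets)
  prev_ages <- as.numeric(unique(
    targets$key[targets$target_class == "prevalence"]))
  fw <- forward_targets(params, lifetable, entry_age = entry_age,
                        horizon_age = horizon_age, band_width = band_width,
                        prevalence_ages = if (length(prev_ages) > 0) prev_ages
                                          else 60)
  key_num <- suppressWarnings(as.numeric(targets$key))
  dplyr::case_when(
    targets$target_class == "incidence" ~
      fw$incidence$rate_per_100k[match(key_num, fw$incidence$age_band_start)],
    targets$target_class == "prevalence" ~
      fw$prevalence$prevalence[match(key_num, fw$prevalence$age)],
    TRUE ~
      fw$stage_distribution$fraction[match(targets$key,
                                           fw$stage_distribution$stage)])
}

#' Calibration objective: weighted squared relative deviations
#'
#' `sum(weight * ((model - target) / max(target, eps))^2)` over all target
#' rows, with the guard `eps` preventing division blow-ups for near-zero
#' targets (1 per 100,000 on the incidence scale, 1e-5 on the fraction
#' scales). Zero iff the model reproduces every target exactly.
#'
#' @param params Natural-history parameter table.
#' @param targets Target tibble (see [validate_targets()]).
#' @param lifetable Annual all-cause lifetable.
#' @param entry_age,horizon_age Model age window in years.
#' @param band_width Incidence band width in years; `NULL` (default) infers
#'   it from the spacing of the incidence target keys.
#' @return Non-negative scalar score.
#' @export
calibration_objective <- function(params, targets, lifetable,
                                  entry_age = 20, horizon_age = 100,
                                  band_width = NULL) {
  targets <- validate_targets(targets)
  if (is.null(band_width)) band_width <- .infer_band_width(targets)
  inc_age <- as.numeric(targets$key[targets$target_class == "incidence"])
  if (length(inc_age) > 0 &&
      (max(inc_age) >= horizon_age || min(inc_age) < entry_age)) {
    stop("incidence target age outside the model horizon", call. = FALSE)
  }
  prev_age <- as.numeric(targets$key[targets$target_class == "prevalence"])
  if (length(prev_age) > 0 &&
      (max(prev_age) > horizon_age || min(prev_age) < entry_age)) {
    stop("prevalence target age outside the model horizon", call. = FALSE)
  }
  model <- .model_values(params, targets, lifetable, entry_age, horizon_age,
                         band_width)
  eps <- ifelse(targets$target_class == "incidence", 1, 1e-5)
  sum(targets$weight * ((model - targets$value) /
                          pmax(targets$value, eps))^2)
}

#' Gaussian logit-scale proposal for calibration parameters
#'
#' Perturbs the masked parameters (every age band of each masked parameter
#' name) by independent Gaussian steps on the logit scale, which keeps every
#' proposal strictly inside (0, 1). Unmasked rows are returned bit-identical.
#'
#' @param params Parameter table.
#' @param step Standard deviation of the logit-scale step; 0 returns `params`
#'   unchanged.
#' @param mask Character vector of parameter names to perturb (non-empty
#'   subset of [nh_param_names()]).
#' @return A new parameter table.
#' @export
propose_params <- function(params, step, mask) {
  if (length(mask) == 0) stop("`mask` must be non-empty", call. = FALSE)
  stopifnot(all(mask %in% nh_param_names()))
  if (step == 0) return(params)
  sel <- params$parameter %in% mask
  p <- pmin(pmax(params$monthly_probability[sel], 1e-12), 1 - 1e-12)
  params$monthly_probability[sel] <-
    .inv_logit(.logit(p) + stats::rnorm(sum(sel), 0, step))
  params
}

#' Annealing schedule
#'
#' @param t0 Initial temperature; `NULL` uses the objective at the starting
#'   parameters of each stage.
#' @param cooling Geometric cooling factor in (0, 1), default 0.95.
#' @param iters_per_temp Iterations between coolings, default 50.
#' @param max_iter Total iteration cap across all stages, default 10,000.
#' @param step Logit-scale proposal standard deviation, default 0.1.
#' @param seed RNG seed for the annealing chain.
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(t0 = NULL, cooling = 0.95, iters_per_temp = 50,
                            max_iter = 10000, step = 0.1, seed = 1L) {
  stopifnot(is.null(t0) || t0 > 0, cooling > 0, cooling < 1,
            iters_per_temp >= 1, max_iter >= 0, step >= 0)
  structure(list(t0 = t0, cooling = cooling,
                 iters_per_temp = as.integer(iters_per_temp),
                 max_iter = as.integer(max_iter), step = step,
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

#' Default stepwise stages
#'
#' Stage 1 fits the age-banded adenoma-onset probabilities against the
#' adenoma-prevalence targets (the only parameters prevalence identifies on
#' its own). Stage 2 fits the adenoma-progression pipeline (low-to-high-risk
#' and high-risk-to-preclinical) once the incidence targets join the score:
#' any-adenoma prevalence is nearly blind to the internal low/high split, so
#' fitting it against prevalence alone would freeze an arbitrary value.
#' Stage 3 fits preclinical stage progression and symptomatic detection with
#' every target active. Stage 4 is a small-step polish over all parameters
#' and all targets: incidence level and stage mix constrain the ratios of
#' the sojourn parameters much more strongly than their common scale, and
#' the final joint stage walks down that shallow valley after the stepwise
#' passes have placed every parameter near its ridge. Earlier stages never
#' touch parameters outside their mask.
#'
#' @return List of stages, each `list(mask, classes, step_scale)`.
#' @export
default_stage_masks <- function() {
  all_classes <- c("prevalence", "incidence", "stage")
  list(
    list(mask = "adenoma_onset", classes = "prevalence", step_scale = 1),
    list(mask = c("lr_to_hr", "hr_to_preclin"),
         classes = c("prevalence", "incidence"), step_scale = 1),
    list(mask = c("local_to_regional", "regional_to_distant",
                  "detect_local", "detect_regional", "detect_distant"),
         classes = all_classes, step_scale = 1),
    list(mask = nh_param_names(), classes = all_classes, step_scale = 0.3)
  )
}

#' Stepwise simulated-annealing calibration
#'
#' Classic Metropolis annealing run stage by stage: each stage perturbs only
#' its masked parameters ([propose_params()]) against its active target
#' classes, always accepting improvements and accepting worsenings with
#' probability `exp(-delta / T)` under a geometrically cooling temperature.
#' The deterministic forward operator ([forward_targets()]) is the objective's
#' engine, so the landscape is noise-free. The best parameters seen in each
#' stage seed the next; the final score is the objective over all targets.
#'
#' @param targets Target tibble.
#' @param schedule An [anneal_schedule()].
#' @param initial_params Starting parameter table.
#' @param stage_masks Stages as in [default_stage_masks()].
#' @param lifetable Annual all-cause lifetable.
#' @param entry_age,horizon_age Model age window.
#' @param band_width Incidence band width in years.
#' @param polish_maxit Simplex-iteration cap per round of the final local
#'   refinement (alternating quasi-Newton and Nelder-Mead rounds on the
#'   logit scale over all annealed parameters, all targets active). The
#'   annealing stages place each parameter near its ridge; the refinement
#'   then descends the shallow valley that couples the sojourn parameters,
#'   which a fixed-step Metropolis chain walks only slowly. 0 disables it.
#' @param restarts Number of independent annealing chains (the iteration
#'   budget is split between them); every chain is polished and the best
#'   polished result is returned.
#' @return A `crc_calibration` list: `best_params`, `best_objective` (over all
#'   targets), `trajectory` (tibble: stage, iteration, temperature, objective,
#'   best_objective, accepted), `acceptance_rate`, `stages` (the masks used).
#' @export
anneal <- function(targets, schedule, initial_params,
                   stage_masks = default_stage_masks(), lifetable,
                   entry_age = 20, horizon_age = 100, band_width = NULL,
                   polish_maxit = 4000, restarts = 5) {
  targets <- validate_targets(targets)
  initial_params <- validate_nh_params(initial_params)
  if (is.null(band_width)) band_width <- .infer_band_width(targets)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(schedule$seed)

  # precomputed fast objective: age bands are fixed during annealing, so
  # parameter expansion reduces to one matrix lookup and the forward
  # recursion runs in compiled code; numerically identical to
  # calibration_objective()
  pidx <- .param_cycle_index(initial_params, entry_age, horizon_age)
  pdeath <- .expand_lifetable(validate_lifetable(lifetable), entry_age,
                              horizon_age)
  prev_ages <- as.numeric(unique(
    targets$key[targets$target_class == "prevalence"]))
  if (length(prev_ages) == 0) prev_ages <- 60
  geom <- .forward_geometry(entry_age, horizon_age, band_width, prev_ages)
  key_num <- suppressWarnings(as.numeric(targets$key))
  slot <- dplyr::case_when(
    targets$target_class == "incidence" ~ match(key_num, geom$bands),
    targets$target_class == "prevalence" ~ match(key_num, prev_ages),
    TRUE ~ match(targets$key, .STAGES))
  if (anyNA(slot)) {
    stop("target key outside the model horizon or band grid: ",
         paste(targets$key[is.na(slot)], collapse = ", "), call. = FALSE)
  }
  denom <- pmax(targets$value, ifelse(targets$target_class == "incidence",
                                      1, 1e-5))
  obj <- function(p, classes) {
    pmat <- matrix(p$monthly_probability[pidx], nrow(pidx), ncol(pidx),
                   dimnames = dimnames(pidx))
    # infeasible proposals (total exit probability above 1) are repelled by
    # a penalty proportional to the violation, keeping the chain and the
    # simplex inside the valid region
    worst <- max(pmat[, "local_to_regional"] + pmat[, "detect_local"] + pdeath,
                 pmat[, "regional_to_distant"] + pmat[, "detect_regional"] +
                   pdeath,
                 pmat[, "detect_distant"] + pdeath)
    if (worst > 1) return(1e6 * worst)
    raw <- .forward_targets_cpp(pmat, pdeath, geom$band_of_cycle,
                                length(geom$bands), geom$prev_read,
                                length(prev_ages))
    inc <- ifelse(raw$pm_band > 0, raw$dx_band / (raw$pm_band / 12) * 1e5, 0)
    tot <- sum(raw$stage_flow)
    stg <- if (tot > 0) raw$stage_flow / tot else rep(NA_real_, 3)
    model <- dplyr::case_when(
      targets$target_class == "incidence" ~ inc[slot],
      targets$target_class == "prevalence" ~ raw$prev[slot],
      TRUE ~ stg[slot])
    act <- targets$target_class %in% classes
    sum(targets$weight[act] *
          ((model[act] - targets$value[act]) / denom[act])^2)
  }

  per_stage <- if (length(stage_masks) > 0)
    schedule$max_iter %/% (length(stage_masks) * restarts) else 0
  all_classes <- unique(targets$target_class)
  traj <- list()
  n_acc <- 0L
  n_tot <- 0L

  run_chain <- function(chain, start) {
    cur <- start
    for (s in seq_along(stage_masks)) {
      st <- stage_masks[[s]]
      f_cur <- obj(cur, st$classes)
      if (!is.finite(f_cur)) {
        stop("non-finite objective at the start of stage ", s, call. = FALSE)
      }
      best <- cur
      f_best <- f_cur
      temp <- if (is.null(schedule$t0)) max(f_cur, 1e-6) else schedule$t0
      step_s <- schedule$step *
        (if (!is.null(st$step_scale)) st$step_scale else 1)
      if (per_stage > 0) {
        for (it in seq_len(per_stage)) {
          cand <- propose_params(cur, step_s, st$mask)
          f_cand <- obj(cand, st$classes)
          if (!is.finite(f_cand)) {
            stop("non-finite objective in stage ", s, ", iteration ", it,
                 call. = FALSE)
          }
          accept <- f_cand <= f_cur ||
            stats::runif(1) < exp(-(f_cand - f_cur) / temp)
          if (accept) {
            cur <- cand
            f_cur <- f_cand
            n_acc <<- n_acc + 1L
            if (f_cur < f_best) {
              best <- cur
              f_best <- f_cur
            }
          }
          n_tot <<- n_tot + 1L
          traj[[length(traj) + 1L]] <<- c(chain = chain, stage = s,
                                          iteration = it,
                                          temperature = temp,
                                          objective = f_cur,
                                          best_objective = f_best,
                                          accepted = as.numeric(accept))
          if (it %% schedule$iters_per_temp == 0) {
            temp <- temp * schedule$cooling
          }
        }
      }
      cur <- best  # next stage starts from this stage's best
    }
    cur
  }

  free <- unique(unlist(lapply(stage_masks, `[[`, "mask")))
  # alternating quasi-Newton and simplex refinement: the quasi-Newton steps
  # descend the shallow coupled-sojourn valley quickly, the simplex
  # re-centres after any kink of the penalty boundary; stops on stagnation
  polish <- function(p0, rounds) {
    if (polish_maxit <= 0 || length(free) == 0 || schedule$max_iter <= 0) {
      return(p0)
    }
    sel <- p0$parameter %in% free
    x <- .logit(pmin(pmax(p0$monthly_probability[sel], 1e-12), 1 - 1e-12))
    fn <- function(xx) {
      p <- p0
      p$monthly_probability[sel] <- .inv_logit(xx)
      obj(p, all_classes)
    }
    f_prev <- fn(x)
    for (round in seq_len(rounds)) {
      op <- stats::optim(x, fn, method = "BFGS",
                         control = list(maxit = 300, reltol = 1e-16))
      op <- stats::optim(op$par, fn, method = "Nelder-Mead",
                         control = list(maxit = polish_maxit,
                                        reltol = 1e-15))
      x <- op$par
      if (f_prev - op$value < 1e-14) break
      f_prev <- op$value
    }
    if (op$value <= obj(p0, all_classes)) {
      p0$monthly_probability[sel] <- .inv_logit(x)
    }
    p0
  }

  # independent annealing chains guard against stray basins; each chain gets
  # a light refinement before the comparison (the basin of the best fit has
  # a far lower floor than its rivals, but not necessarily a lower
  # un-polished objective), then the winner is refined to convergence
  cur <- initial_params
  f_overall <- Inf
  for (chain in seq_len(restarts)) {
    start <- initial_params
    if (chain > 1) {
      # later chains start from a jittered copy of the initial parameters
      # (logit-scale Gaussian, sd 0.3) so the chains explore different
      # basins rather than re-running the same walk with fresh noise
      pp <- pmin(pmax(start$monthly_probability, 1e-12), 1 - 1e-12)
      start$monthly_probability <-
        .inv_logit(.logit(pp) + stats::rnorm(nrow(start), 0, 0.3))
    }
    # every chain is refined to convergence before the comparison: rival
    # basins can match the truth basin's objective under a shallow polish,
    # and the refinement stops early on stagnation so wrong basins are
    # cheap to rule out
    cand <- polish(run_chain(chain, start), rounds = 5)
    f_cand <- obj(cand, all_classes)
    if (f_cand < f_overall) {
      cur <- cand
      f_overall <- f_cand
    }
  }
  cur <- polish(cur, rounds = 5)

  trajectory <- if (length(traj) > 0) {
    tibble::as_tibble(do.call(rbind, traj))
  } else {
    tibble::tibble(chain = numeric(), stage = numeric(),
                   iteration = numeric(), temperature = numeric(),
                   objective = numeric(), best_objective = numeric(),
                   accepted = numeric())
  }

  structure(list(
    best_params = cur,
    best_objective = calibration_objective(cur, targets, lifetable,
                                           entry_age, horizon_age, band_width),
    trajectory = trajectory,
    acceptance_rate = if (n_tot > 0) n_acc / n_tot else NA_real_,
    stages = stage_masks,
    schedule = schedule),
    class = "crc_calibration")
}

#' @export
print.crc_calibration <- function(x, ...) {
  cat("<crc_calibration> objective ", signif(x$best_objective, 4),
      ", acceptance rate ", signif(x$acceptance_rate, 3), "\n", sep = "")
  invisible(x)
}

#' Compare calibrated parameters against holdout targets
#'
#' @param result A `crc_calibration` (or a bare parameter table).
#' @param holdout_targets Target tibble to evaluate against.
#' @param lifetable Annual all-cause lifetable.
#' @param tolerance Relative deviation above which a row is flagged.
#' @param entry_age,horizon_age,band_width Model settings.
#' @return Tibble: target columns plus `model`, `relative_deviation`,
#'   `flagged`; zero rows (with attribute `empty_holdout = TRUE`) for an
#'   empty holdout.
#' @export
validate_calibration <- function(result, holdout_targets, lifetable,
                                 tolerance = 0.25, entry_age = 20,
                                 horizon_age = 100, band_width = NULL) {
  params <- if (inherits(result, "crc_calibration")) result$best_params
            else result
  if (nrow(holdout_targets) == 0) {
    out <- tibble::tibble(target_class = character(), key = character(),
                          value = numeric(), weight = numeric(),
                          model = numeric(), relative_deviation = numeric(),
                          flagged = logical())
    attr(out, "empty_holdout") <- TRUE
    return(out)
  }
  holdout_targets <- validate_targets(holdout_targets)
  model <- .model_values(params, holdout_targets, lifetable, entry_age,
                         horizon_age, band_width)
  eps <- ifelse(holdout_targets$target_class == "incidence", 1, 1e-5)
  out <- dplyr::mutate(
    holdout_targets,
    model = model,
    relative_deviation = abs(model - .data$value) / pmax(.data$value, eps),
    flagged = .data$relative_deviation > tolerance)
  attr(out, "empty_holdout") <- FALSE
  out
}
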
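#' Deterministic expected-occupancy oracle for the natural-history model
#'
#' Computes the exact expected state occupancy by cycle via forward recursion
#' of the per-cycle transition probabilities, tracking diagnosed persons by
#' months since diagnosis so the 10-year stage-specific mortality window is
#' applied exactly as in the microsimulation. Microsimulation mean occupancy
#' converges to this trajectory as the cohort grows; the package's tests use
#' it as the independent check on the stochastic engine, and calibration uses
#' a reduced version of the same recursion as its noise-free forward operator.
#'
#' @inheritParams simulate_cohort
#' @return Matrix of occupancy fractions, `(cycles + 1) x 11`, rows indexed
#'   from cycle 0 (model entry), columns named by [crc_states()].
#' @export
cohort_matrix_oracle <- function(params, lifetable, survival,
                                 entry_age = 20, horizon_age = 100) {
  params <- validate_nh_params(params)
  lifetable <- validate_lifetable(lifetable)
  survival <- validate_stage_survival(survival)
  pmat <- .expand_params(params, entry_age, horizon_age)
  pdeath <- .expand_lifetable(lifetable, entry_age, horizon_age)
  .check_exit_probs(pmat, pdeath)
  pcancer <- .expand_stage_survival(survival)
  n_cycles <- nrow(pmat)

  # live pre-diagnosis states
  v <- c(Healthy = 1, AdenomaLR = 0, AdenomaHR = 0,
         PreclinLocal = 0, PreclinRegional = 0, PreclinDistant = 0)
  # diagnosed persons by stage (rows) and months since diagnosis 1..121
  # (column 121 aggregates months > 120: past the excess-mortality window)
  clin <- matrix(0, 3, 121)
  d_crc <- 0
  d_other <- 0

  occ <- matrix(0, n_cycles + 1, 11, dimnames = list(NULL, crc_states()))
  snap <- function() c(v, rowSums(clin), d_crc, d_other)
  occ[1, ] <- snap()
  # monthly cancer mortality by stage (rows) and month since dx 1..121;
  # the 121 bucket is beyond the 10-year window, so excess risk is 0 there
  pcm <- cbind(t(pcancer), 0)

  for (t in seq_len(n_cycles)) {
    p <- pmat[t, ]
    pd <- pdeath[t]

    new_dx <- c(v["PreclinLocal"] * p["detect_local"],
                v["PreclinRegional"] * p["detect_regional"],
                v["PreclinDistant"] * p["detect_distant"])

    v_new <- v
    v_new["Healthy"] <- v["Healthy"] * (1 - p["adenoma_onset"] - pd)
    v_new["AdenomaLR"] <- v["AdenomaLR"] * (1 - p["lr_to_hr"] - pd) +
      v["Healthy"] * p["adenoma_onset"]
    v_new["AdenomaHR"] <- v["AdenomaHR"] * (1 - p["hr_to_preclin"] - pd) +
      v["AdenomaLR"] * p["lr_to_hr"]
    v_new["PreclinLocal"] <- v["PreclinLocal"] *
      (1 - p["local_to_regional"] - p["detect_local"] - pd) +
      v["AdenomaHR"] * p["hr_to_preclin"]
    v_new["PreclinRegional"] <- v["PreclinRegional"] *
      (1 - p["regional_to_distant"] - p["detect_regional"] - pd) +
      v["PreclinLocal"] * p["local_to_regional"]
    v_new["PreclinDistant"] <- v["PreclinDistant"] *
      (1 - p["detect_distant"] - pd) +
      v["PreclinRegional"] * p["regional_to_distant"]

    d_other <- d_other + sum(v) * pd + sum(clin) * pd
    # clinical dynamics: months 1..120 face cancer + all-cause risk, the
    # 121 bucket only all-cause; everyone advances one month
    d_crc <- d_crc + sum(clin * pcm)
    surv_frac <- 1 - pcm - pd
    clin_next <- matrix(0, 3, 121)
    clin_next[, 2:120] <- (clin * surv_frac)[, 1:119]
    clin_next[, 121] <- (clin * surv_frac)[, 120] + (clin * surv_frac)[, 121]
    clin_next[, 1] <- new_dx
    clin <- clin_next
    v <- v_new

    occ[t + 1, ] <- snap()
  }
  occ
}

#' Fast forward operator for calibration targets
#'
#' A reduced deterministic recursion over the six pre-diagnosis states that
#' accumulates the quantities calibration targets refer to: age-specific
#' incidence of diagnosed cancer per 100,000 alive-and-undiagnosed
#' person-years, adenoma prevalence by age among alive undiagnosed persons,
#' the stage distribution at diagnosis, and the lifetime fraction diagnosed.
#' Diagnosed persons leave the risk pool, so post-diagnosis survival does not
#' enter — which is what makes this operator cheap enough to sit inside the
#' simulated-annealing loop.
#'
#' @inheritParams cohort_matrix_oracle
#' @param band_width Incidence age-band width in years.
#' @param prevalence_ages Ages (years) at which adenoma prevalence is read.
#' @return List with `incidence` (tibble: age_band_start, rate_per_100k),
#'   `prevalence` (tibble: age, prevalence), `stage_distribution` (tibble:
#'   stage, fraction), `lifetime_incidence` (fraction of the cohort ever
#'   diagnosed).
#' @export
forward_targets <- function(params, lifetable, survival = NULL,
                            entry_age = 20, horizon_age = 100,
                            band_width = 5,
                            prevalence_ages = seq(40, 80, by = 10)) {
  params <- validate_nh_params(params)
  lifetable <- validate_lifetable(lifetable)
  pmat <- .expand_params(params, entry_age, horizon_age)
  pdeath <- .expand_lifetable(lifetable, entry_age, horizon_age)
  .check_exit_probs(pmat, pdeath)
  geom <- .forward_geometry(entry_age, horizon_age, band_width,
                            prevalence_ages)
  raw <- .forward_targets_cpp(pmat, pdeath, geom$band_of_cycle,
                              length(geom$bands), geom$prev_read,
                              length(prevalence_ages))
  .forward_summaries(raw, geom, prevalence_ages)
}

# cycle-to-band and prevalence-readout index vectors for the C++ recursion
.forward_geometry <- function(entry_age, horizon_age, band_width,
                              prevalence_ages) {
  n_cycles <- (horizon_age - entry_age) * 12
  ages <- entry_age + (0:(n_cycles - 1)) %/% 12
  bands <- (ages %/% band_width) * band_width
  ub <- sort(unique(bands))
  age_m <- entry_age * 12 + 0:(n_cycles - 1)
  prev_read <- rep(-1L, n_cycles)
  slot <- match(age_m %/% 12, prevalence_ages)
  hit <- age_m %% 12 == 0 & !is.na(slot)
  prev_read[hit] <- as.integer(slot[hit] - 1L)
  list(band_of_cycle = as.integer(match(bands, ub) - 1L), bands = ub,
       prev_read = prev_read)
}

.forward_summaries <- function(raw, geom, prevalence_ages) {
  total_dx <- sum(raw$stage_flow)
  list(
    incidence = tibble::tibble(
      age_band_start = geom$bands,
      rate_per_100k = ifelse(raw$pm_band > 0,
                             raw$dx_band / (raw$pm_band / 12) * 1e5, 0)),
    prevalence = tibble::tibble(age = prevalence_ages,
                                prevalence = raw$prev),
    stage_distribution = tibble::tibble(
      stage = .STAGES,
      fraction = if (total_dx > 0) as.numeric(raw$stage_flow) / total_dx
                 else rep(NA_real_, 3)),
    lifetime_incidence = total_dx)
}

# row index into `params` for every (cycle, parameter) pair; bands are fixed
# during annealing, so repeated expansion reduces to one matrix lookup
.param_cycle_index <- function(params, entry_age = 20, horizon_age = 100) {
  n_cycles <- (horizon_age - entry_age) * 12
  ages <- entry_age + (0:(n_cycles - 1)) %/% 12
  out <- matrix(0L, n_cycles, length(nh_param_names()),
                dimnames = list(NULL, nh_param_names()))
  rows <- seq_len(nrow(params))
  for (pm in nh_param_names()) {
    sel <- which(params$parameter == pm)
    b <- params[sel, ]
    ord <- order(b$age_band_start)
    idx <- findInterval(ages, b$age_band_start[ord])
    out[, pm] <- sel[ord][idx]
  }
  out
}
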
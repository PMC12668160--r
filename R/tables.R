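#' Input tables: lifetable, stage survival, natural-history parameters
#'
#' Three delimited-text tables drive the natural-history simulation:
#'
#' * a **lifetable** with columns `age` (integer years) and `qx` (annual
#'   all-cause death probability), covering every age from 20 to 100;
#' * a **stage-survival** table with columns `stage` (`local`, `regional`,
#'   `distant`), `year` (1-10 since diagnosis) and `qx_cancer` (annual
#'   cancer-specific death probability) — excess mortality is zero beyond
#'   year 10;
#' * a **natural-history parameter** table with columns `parameter`,
#'   `age_band_start`, `age_band_end` and `monthly_probability`, holding the
#'   eight age-banded monthly transition probabilities (see
#'   [nh_param_names()]); bands are half-open on the right except the last,
#'   and must tile 20-100 for every parameter.
#'
#' `read_*`/`write_*` round-trip these tables through CSV; `validate_*` checks
#' the invariants and is called by every consumer.
#'
#' @name input-tables
NULL

#' @rdname input-tables
#' @param path File path of a CSV table.
#' @return A tibble of the corresponding table.
#' @export
read_lifetable <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  validate_lifetable(tb)
}

#' @rdname input-tables
#' @param lifetable Tibble with columns `age`, `qx`.
#' @export
validate_lifetable <- function(lifetable) {
  stopifnot(all(c("age", "qx") %in% names(lifetable)))
  if (!all(20:100 %in% lifetable$age)) {
    stop("lifetable must cover every age 20-100", call. = FALSE)
  }
  if (any(lifetable$qx < 0 | lifetable$qx > 1 | !is.finite(lifetable$qx))) {
    stop("lifetable qx values must lie in [0, 1]", call. = FALSE)
  }
  dplyr::arrange(tibble::as_tibble(lifetable), .data$age)
}

#' @rdname input-tables
#' @export
read_stage_survival <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  validate_stage_survival(tb)
}

#' @rdname input-tables
#' @param survival Tibble with columns `stage`, `year`, `qx_cancer`.
#' @export
validate_stage_survival <- function(survival) {
  stopifnot(all(c("stage", "year", "qx_cancer") %in% names(survival)))
  need <- tidyr::expand_grid(stage = .STAGES, year = 1:10)
  have <- dplyr::distinct(survival, .data$stage, .data$year)
  if (nrow(dplyr::anti_join(need, have, by = c("stage", "year"))) > 0) {
    stop("stage survival must cover stages local/regional/distant, years 1-10",
         call. = FALSE)
  }
  if (any(survival$qx_cancer < 0 | survival$qx_cancer > 1)) {
    stop("qx_cancer values must lie in [0, 1]", call. = FALSE)
  }
  dplyr::arrange(tibble::as_tibble(survival), .data$stage, .data$year)
}

#' @rdname input-tables
#' @export
read_nh_params <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  validate_nh_params(tb)
}

#' @rdname input-tables
#' @param params Tibble with columns `parameter`, `age_band_start`,
#'   `age_band_end`, `monthly_probability`.
#' @export
validate_nh_params <- function(params) {
  cols <- c("parameter", "age_band_start", "age_band_end", "monthly_probability")
  stopifnot(all(cols %in% names(params)))
  bad <- setdiff(unique(params$parameter), nh_param_names())
  if (length(bad) > 0) {
    stop("unknown natural-history parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(nh_param_names(), unique(params$parameter))
  if (length(missing) > 0) {
    stop("missing natural-history parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- params$monthly_probability
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("monthly probabilities must lie in [0, 1]", call. = FALSE)
  }
  # bands must tile [20, 100] per parameter
  for (pm in nh_param_names()) {
    b <- dplyr::arrange(dplyr::filter(params, .data$parameter == pm),
                        .data$age_band_start)
    if (b$age_band_start[1] > 20 || b$age_band_end[nrow(b)] < 100 ||
        (nrow(b) > 1 && any(b$age_band_start[-1] != b$age_band_end[-nrow(b)]))) {
      stop("age bands for '", pm, "' must tile ages 20-100 without gaps",
           call. = FALSE)
    }
  }
  dplyr::arrange(tibble::as_tibble(params), .data$parameter,
                 .data$age_band_start)
}

# CSV writer for numeric tables: doubles are serialised through
# as.character (15 significant digits, trailing zeros trimmed), which is
# stable under a write-read-write cycle at the file level
.write_table_csv <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double), as.character))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname input-tables
#' @param x Table to write.
#' @export
write_nh_params <- function(x, path) {
  .write_table_csv(x, path)
}

#' @rdname input-tables
#' @export
write_lifetable <- function(x, path) {
  .write_table_csv(x, path)
}

#' @rdname input-tables
#' @export
write_stage_survival <- function(x, path) {
  .write_table_csv(x, path)
}

#' Build a compact natural-history parameter table from per-parameter bands
#'
#' Convenience constructor: `values` is a named list; each element is either a
#' single probability (constant over ages 20-100) or a tibble/data.frame with
#' `age_band_start`, `age_band_end`, `monthly_probability`.
#'
#' @param values Named list over [nh_param_names()].
#' @return A validated parameter tibble.
#' @export
nh_params <- function(values) {
  rows <- purrr::imap(values, function(v, nm) {
    if (is.numeric(v) && length(v) == 1) {
      tibble::tibble(parameter = nm, age_band_start = 20, age_band_end = 100,
                     monthly_probability = v)
    } else {
      tibble::tibble(parameter = nm,
                     age_band_start = v$age_band_start,
                     age_band_end = v$age_band_end,
                     monthly_probability = v$monthly_probability)
    }
  })
  validate_nh_params(dplyr::bind_rows(rows))
}

# ---- cycle expansion ------------------------------------------------------

# expand banded parameters to a (n_cycles x 8) matrix of monthly probabilities,
# cycle t covering age [entry + t, entry + t + 1) months
.expand_params <- function(params, entry_age = 20, horizon_age = 100) {
  n_cycles <- (horizon_age - entry_age) * 12
  ages <- entry_age + (0:(n_cycles - 1)) %/% 12   # completed years at cycle
  out <- matrix(0, n_cycles, length(nh_param_names()),
                dimnames = list(NULL, nh_param_names()))
  for (pm in nh_param_names()) {
    b <- dplyr::filter(params, .data$parameter == pm)
    b <- dplyr::arrange(b, .data$age_band_start)
    idx <- findInterval(ages, b$age_band_start)
    bad <- idx < 1 | ages > b$age_band_end[pmax(idx, 1)]
    if (any(bad)) {
      stop("no age band for parameter '", pm, "' at age ", ages[which(bad)[1]],
           call. = FALSE)
    }
    out[, pm] <- b$monthly_probability[idx]
  }
  out
}

# monthly all-cause death probability per cycle from the annual lifetable
.expand_lifetable <- function(lifetable, entry_age = 20, horizon_age = 100) {
  n_cycles <- (horizon_age - entry_age) * 12
  ages <- entry_age + (0:(n_cycles - 1)) %/% 12
  qx <- lifetable$qx[match(ages, lifetable$age)]
  if (anyNA(qx)) stop("lifetable missing ages needed by the horizon", call. = FALSE)
  annual_to_monthly(qx)
}

# monthly cancer-specific death probability, months since diagnosis 1..120
# (rows) by stage (columns local/regional/distant); year = ceil(m/12)
.expand_stage_survival <- function(survival) {
  out <- matrix(0, 120, 3, dimnames = list(NULL, .STAGES))
  for (s in .STAGES) {
    b <- dplyr::filter(survival, .data$stage == s)
    yr <- ((1:120) - 1) %/% 12 + 1
    out[, s] <- annual_to_monthly(b$qx_cancer[match(yr, b$year)])
  }
  out
}

# check the exit-probability invariant: for every state and cycle the total
# exit probability (disease exits + all-cause death) must not exceed 1
.check_exit_probs <- function(pmat, pdeath) {
  exits <- cbind(
    healthy = pmat[, "adenoma_onset"],
    adenoma_lr = pmat[, "lr_to_hr"],
    adenoma_hr = pmat[, "hr_to_preclin"],
    preclin_local = pmat[, "local_to_regional"] + pmat[, "detect_local"],
    preclin_regional = pmat[, "regional_to_distant"] + pmat[, "detect_regional"],
    preclin_distant = pmat[, "detect_distant"]
  ) + pdeath
  if (any(exits > 1 + 1e-12)) {
    bad <- which(exits > 1 + 1e-12, arr.ind = TRUE)
    stop("exit probabilities exceed 1 for state '", colnames(exits)[bad[1, 2]],
         "' at cycle ", bad[1, 1] - 1, call. = FALSE)
  }
  invisible(TRUE)
}
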
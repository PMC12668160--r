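#' Convert an annual probability to a monthly probability
#'
#' Uses the constant-hazard conversion `1 - (1 - p)^(1/12)`, so that twelve
#' independent monthly applications reproduce the annual risk.
#'
#' @param p_annual Annual probability (or vector), each in \[0, 1\].
#' @return Monthly probability of the same length.
#' @examples
#' annual_to_monthly(0.12)
#' monthly_to_annual(annual_to_monthly(0.12))
#' @export
annual_to_monthly <- function(p_annual) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    stop("`p_annual` must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / 12)
}

#' @rdname annual_to_monthly
#' @param p_monthly Monthly probability (or vector), each in \[0, 1\].
#' @export
monthly_to_annual <- function(p_monthly) {
  if (any(!is.finite(p_monthly)) || any(p_monthly < 0) || any(p_monthly > 1)) {
    stop("`p_monthly` must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_monthly)^12
}

#' Discounting of costs and health accrued at a model time
#'
#' Values are discounted at an annual rate applied at monthly resolution:
#' a value accrued `t` months after model start is multiplied by
#' `(1 + rate)^(-t/12)`. The base-case rate is 3\% per annum; rate 0 is the
#' identity. The discounting clock starts at model entry (age 20).
#'
#' @param value Amount (money or life-years) accrued at time `t_months`.
#' @param t_months Months since model start (non-negative).
#' @param rate Annual discount rate, default 0.03.
#' @return Discounted value.
#' @examples
#' discount(1, 12)          # 1/1.03
#' discount(100, 0)         # undiscounted at t = 0
#' @export
discount <- function(value, t_months, rate = 0.03) {
  if (any(t_months < 0)) stop("`t_months` must be non-negative", call. = FALSE)
  value * (1 + rate)^(-t_months / 12)
}

# discounted sum of a constant monthly stream of `per_month` from month `from`
# for `n_months` months: per_month * sum_{t=from}^{from+n-1} r^t,
# r = (1+rate)^(-1/12). Closed form; rate 0 degenerates to per_month * n.
.discounted_stream <- function(per_month, from, n_months, rate = 0.03) {
  n_months <- pmax(n_months, 0)
  if (rate == 0) return(per_month * n_months)
  r <- (1 + rate)^(-1 / 12)
  per_month * r^from * (1 - r^n_months) / (1 - r)
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))
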
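#' Convert an instantaneous rate to a per-cycle transition probability
#'
#' Transition evidence is often reported as an event rate per unit time
#' (e.g. recoveries per person-year) while a discrete-time cohort model
#' needs per-cycle probabilities. Under a constant hazard the two are
#' linked by `p = 1 - exp(-r * t)`.
#'
#' @param rate Non-negative event rate per year (vectorised).
#' @param cycle_length Cycle length in years, strictly positive.
#' @return Probability in `[0, 1)`, same length as `rate`.
#' @seealso [prob_to_rate()] for the inverse transform.
#' @examples
#' rate_to_prob(0.1, 1)     # 1 - exp(-0.1)
#' prob_to_rate(rate_to_prob(0.5, 2), 2)
#' @export
rate_to_prob <- function(rate, cycle_length = 1) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be finite and >= 0.", call. = FALSE)
  }
  if (length(cycle_length) != 1L || !is.finite(cycle_length) || cycle_length <= 0) {
    stop("`cycle_length` must be a single positive number of years.", call. = FALSE)
  }
  1 - exp(-rate * cycle_length)
}

#' Convert a per-cycle probability back to an instantaneous rate
#'
#' Inverse of [rate_to_prob()]: `r = -log(1 - p) / t`. A probability of
#' exactly 1 corresponds to an infinite hazard and is rejected.
#'
#' @param prob Probability in `[0, 1)` (vectorised).
#' @param cycle_length Cycle length in years, strictly positive.
#' @return Non-negative rate per year.
#' @export
prob_to_rate <- function(prob, cycle_length = 1) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob >= 1)) {
    stop("`prob` must lie in [0, 1); a probability of 1 has no finite rate.",
         call. = FALSE)
  }
  if (length(cycle_length) != 1L || !is.finite(cycle_length) || cycle_length <= 0) {
    stop("`cycle_length` must be a single positive number of years.", call. = FALSE)
  }
  -log(1 - prob) / cycle_length
}

#' Discount factor for a given cycle
#'
#' Standard annual compound discounting evaluated at the end of cycle
#' `cycle_index`: `(1 + rate)^(-cycle_index * cycle_length)`.
#'
#' @param cycle_index Integer cycle index >= 0 (vectorised).
#' @param annual_rate Annual discount rate as a fraction, >= 0.
#' @param cycle_length Cycle length in years.
#' @return Discount factor in `(0, 1]`; exactly 1 when `annual_rate = 0`
#'   or `cycle_index = 0`.
#' @examples
#' discount_factor(0:5, 0.03)
#' @export
discount_factor <- function(cycle_index, annual_rate, cycle_length = 1) {
  if (any(cycle_index < 0)) stop("`cycle_index` must be >= 0.", call. = FALSE)
  if (length(annual_rate) != 1L || !is.finite(annual_rate) || annual_rate < 0) {
    stop("`annual_rate` must be a single non-negative fraction.", call. = FALSE)
  }
  (1 + annual_rate)^(-cycle_index * cycle_length)
}
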
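#' Analysis settings for outcome accumulation
#'
#' Bundles the economic evaluation settings: separate annual discount
#' rates for effects and costs (both default 3%/yr), the willingness to
#' pay per QALY (lambda), the costing perspective, half-cycle correction,
#' the time horizon in cycles and the admissible utility range. The
#' default utility range is `[0, 1]` (0 = death, 1 = full health); set
#' `utility_bounds = c(-1, 1)` where the EQ-5D value set in use admits
#' states worse than dead.
#'
#' @param discount_rate_effects,discount_rate_costs Annual discount rates
#'   as fractions, `>= 0`.
#' @param lambda Willingness to pay per QALY, `> 0`, in the analysis
#'   currency.
#' @param perspective `"healthcare"` (payer costs only) or `"societal"`
#'   (healthcare plus social-care and patient-borne costs).
#' @param half_cycle_correction Logical; average adjacent occupancy rows
#'   (trapezoid) so that transitions are effectively assumed to happen
#'   mid-cycle. Default `TRUE`.
#' @param horizon_cycles Time horizon in cycles, `>= 1`.
#' @param utility_bounds Length-2 admissible utility range.
#' @param currency Currency label, reporting only; no conversion.
#' @return An object of class `outcome_settings`.
#' @export
outcome_settings <- function(discount_rate_effects = 0.03,
                             discount_rate_costs = 0.03,
                             lambda = 30000,
                             perspective = c("societal", "healthcare"),
                             half_cycle_correction = TRUE,
                             horizon_cycles = 30L,
                             utility_bounds = c(0, 1),
                             currency = "EUR") {
  perspective <- match.arg(perspective)
  if (discount_rate_effects < 0 || discount_rate_costs < 0) {
    stop("discount rates must be >= 0.", call. = FALSE)
  }
  if (!is.numeric(lambda) || lambda <= 0) {
    stop("`lambda` (willingness to pay per QALY) must be > 0.", call. = FALSE)
  }
  if (horizon_cycles < 1) stop("`horizon_cycles` must be >= 1.", call. = FALSE)
  if (length(utility_bounds) != 2L || utility_bounds[1] >= utility_bounds[2]) {
    stop("`utility_bounds` must be an increasing length-2 range.",
         call. = FALSE)
  }
  structure(
    list(discount_rate_effects = discount_rate_effects,
         discount_rate_costs = discount_rate_costs,
         lambda = lambda, perspective = perspective,
         half_cycle_correction = isTRUE(half_cycle_correction),
         horizon_cycles = as.integer(horizon_cycles),
         utility_bounds = as.numeric(utility_bounds),
         currency = currency),
    class = "outcome_settings"
  )
}

#' Accumulate discounted QALYs and costs over a cohort trace
#'
#' Rewards accrue from cycle 1 onward: the contribution of cycle `t` is
#' `discount_factor(t) * (occupancy_t . value_vector) * cycle_length`,
#' where under half-cycle correction `occupancy_t` is replaced by the mean
#' of the occupancy rows at `t-1` and `t` (membership is then effectively
#' counted mid-cycle). Effects use `discount_rate_effects`, costs use
#' `discount_rate_costs`. Life years (utility-free survival, discounted at
#' the effect rate) are reported as a diagnostic.
#'
#' @param trace A `cohort_trace`.
#' @param values Tibble of [state_values()], one row per trace state.
#' @param settings An [outcome_settings()].
#' @return An `arm_outcome` with fields `qalys`, `life_years`,
#'   `cost_healthcare`, `cost_societal` and
#'   `cost_total_for_perspective`, all per cohort member and discounted.
#' @examples
#' spec <- three_state_spec(0.1, 0.05, mortality = 0.01,
#'                          utilities = c(baseline = 0.8, deteriorated = 0.6))
#' tr <- run_cohort_trace(spec, 10)
#' accumulate_arm(tr, spec$values, outcome_settings(horizon_cycles = 10))
#' @export
accumulate_arm <- function(trace, values, settings) {
  ids <- attr(trace, "states")$id
  if (!setequal(values$state, ids)) {
    stop("`values` states do not match the trace states.", call. = FALSE)
  }
  lb <- settings$utility_bounds
  alive <- ids[!attr(trace, "states")$absorbing]
  u_alive <- values$utility[match(alive, values$state)]
  if (any(u_alive < lb[1] - 1e-12) || any(u_alive > lb[2] + 1e-12)) {
    stop("state utilities outside the configured bounds [",
         lb[1], ", ", lb[2], "].", call. = FALSE)
  }
  occ <- trace_matrix(trace)
  ord <- match(ids, values$state)
  u <- values$utility[ord]
  ch <- values$cost_healthcare[ord]
  cs <- values$cost_societal[ord]
  alive_vec <- as.numeric(!attr(trace, "states")$absorbing)

  cl <- attr(trace, "cycle_length")
  t_idx <- seq_len(nrow(occ) - 1L)              # cycles 1..T
  eff_occ <- occ[t_idx + 1L, , drop = FALSE]
  if (settings$half_cycle_correction) {
    eff_occ <- (occ[t_idx, , drop = FALSE] + eff_occ) / 2
  }
  df_e <- discount_factor(t_idx, settings$discount_rate_effects, cl)
  df_c <- discount_factor(t_idx, settings$discount_rate_costs, cl)

  qalys <- sum(df_e * (eff_occ %*% u)) * cl
  life_years <- sum(df_e * (eff_occ %*% alive_vec)) * cl
  cost_healthcare <- sum(df_c * (eff_occ %*% ch)) * cl
  cost_societal <- sum(df_c * (eff_occ %*% cs)) * cl
  total <- if (settings$perspective == "societal") {
    cost_healthcare + cost_societal
  } else {
    cost_healthcare
  }
  structure(
    list(qalys = qalys, life_years = life_years,
         cost_healthcare = cost_healthcare, cost_societal = cost_societal,
         cost_total_for_perspective = total,
         perspective = settings$perspective),
    class = "arm_outcome"
  )
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf(
    "<arm_outcome> QALYs %.4f | LYs %.4f | healthcare %.2f | societal %.2f | total (%s) %.2f\n",
    x$qalys, x$life_years, x$cost_healthcare, x$cost_societal,
    x$perspective, x$cost_total_for_perspective))
  invisible(x)
}

#' Intervention delivery cost
#'
#' The cost of implementing and delivering the intervention itself, on top
#' of state-attached care costs: a one-off component charged at cycle 0
#' (undiscounted) plus a per-cycle component charged at cycles 1..horizon
#' and discounted at the cost rate.
#'
#' @param one_off One-off cost at cycle 0, `>= 0`.
#' @param per_cycle Recurring cost per cycle, `>= 0`.
#' @return A list of class `intervention_cost`.
#' @export
intervention_cost <- function(one_off = 0, per_cycle = 0) {
  if (one_off < 0 || per_cycle < 0) {
    stop("intervention delivery costs must be >= 0.", call. = FALSE)
  }
  structure(list(one_off = one_off, per_cycle = per_cycle),
            class = "intervention_cost")
}

discounted_delivery_cost <- function(cost, settings, cycle_length = 1) {
  if (is.null(cost)) return(0)
  t_idx <- seq_len(settings$horizon_cycles)
  cost$one_off +
    cost$per_cycle * sum(discount_factor(t_idx, settings$discount_rate_costs,
                                         cycle_length))
}

#' Incremental cost-effectiveness summary of intervention vs control
#'
#' Computes the incremental health effect `delta_e = E_int - E_ctl` (in
#' QALYs), the incremental cost `delta_c` (including the discounted
#' intervention delivery cost), the incremental net monetary benefit
#' `INMB = delta_e * lambda - delta_c`, and classifies the point on the
#' cost-effectiveness plane. The ICER `delta_c / delta_e` is reported only
#' in the trade-off quadrants (NE: more effect at more cost; SW: less
#' effect at a saving); under dominance a ratio is not meaningful and is
#' returned as `NA`.
#'
#' @param intervention,control `arm_outcome` objects computed under the
#'   same settings.
#' @param settings The shared [outcome_settings()].
#' @param delivery_cost Optional [intervention_cost()] for the
#'   intervention arm.
#' @param cycle_length Years per cycle, for discounting the per-cycle
#'   delivery component.
#' @return An `incremental_result` with fields `delta_e`, `delta_c`,
#'   `icer`, `inmb`, `dominance`, `lambda`.
#' @examples
#' a <- structure(list(qalys = 5.25, cost_total_for_perspective = 12000),
#'                class = "arm_outcome")
#' b <- structure(list(qalys = 5.00, cost_total_for_perspective = 10000),
#'                class = "arm_outcome")
#' incremental(a, b, outcome_settings(lambda = 30000))
#' @export
incremental <- function(intervention, control, settings,
                        delivery_cost = NULL, cycle_length = 1) {
  delta_e <- intervention$qalys - control$qalys
  delta_c <- (intervention$cost_total_for_perspective +
                discounted_delivery_cost(delivery_cost, settings,
                                         cycle_length)) -
    control$cost_total_for_perspective
  inmb <- delta_e * settings$lambda - delta_c
  if (delta_e == 0 && delta_c == 0) {
    dominance <- "equivalent"
    icer <- NA_real_
  } else if (delta_e > 0 && delta_c > 0) {
    dominance <- "trade_off_ne_quadrant"
    icer <- delta_c / delta_e
  } else if (delta_e < 0 && delta_c < 0) {
    dominance <- "trade_off_sw_quadrant"
    icer <- delta_c / delta_e
  } else if (delta_e >= 0 && delta_c <= 0) {
    dominance <- "intervention_dominant"
    icer <- NA_real_
  } else {
    dominance <- "comparator_dominant"
    icer <- NA_real_
  }
  structure(
    list(delta_e = delta_e, delta_c = delta_c, icer = icer, inmb = inmb,
         dominance = dominance, lambda = settings$lambda),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> dE = %.5f QALYs, dC = %.2f\n",
              x$delta_e, x$delta_c))
  if (is.na(x$icer)) {
    cat("  ICER: not reported (", x$dominance, ")\n", sep = "")
  } else {
    cat(sprintf("  ICER: %.2f per QALY (%s)\n", x$icer, x$dominance))
  }
  cat(sprintf("  INMB at lambda = %s: %.2f\n",
              format(x$lambda, big.mark = ","), x$inmb))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @method tidy arm_outcome
tidy.arm_outcome <- function(x, ...) {
  tibble::tibble(
    qalys = x$qalys, life_years = x$life_years,
    cost_healthcare = x$cost_healthcare, cost_societal = x$cost_societal,
    cost_total_for_perspective = x$cost_total_for_perspective,
    perspective = x$perspective
  )
}

#' @export
#' @method tidy incremental_result
tidy.incremental_result <- function(x, ...) {
  tibble::tibble(delta_e = x$delta_e, delta_c = x$delta_c, icer = x$icer,
                 inmb = x$inmb, dominance = x$dominance, lambda = x$lambda)
}
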
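#' Define a health state
#'
#' A health state is one of the mutually exclusive compartments a cohort
#' member can occupy. Exactly one state in a model must be absorbing
#' (death): once entered it is never left and it carries zero utility and
#' zero cost.
#'
#' @param id Short unique identifier string.
#' @param label Human-readable name; defaults to `id`.
#' @param absorbing Logical; is this the death state?
#' @return A one-row tibble with columns `id`, `label`, `absorbing`.
#'   Bind rows of several calls to form the state table of a model.
#' @examples
#' dplyr::bind_rows(
#'   health_state("well"),
#'   health_state("sick", "deteriorated health"),
#'   health_state("dead", absorbing = TRUE)
#' )
#' @export
health_state <- function(id, label = id, absorbing = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  tibble::tibble(id = id, label = label, absorbing = isTRUE(absorbing))
}

#' Define a transition between two health states
#'
#' A transition carries either a per-cycle probability (`scale =
#' "probability"`) or an instantaneous per-year rate (`scale = "rate"`,
#' converted with [rate_to_prob()] at matrix-build time). Mortality from a
#' diseased state is usually expressed *relative to* background mortality;
#' the `type` argument selects how the excess is composed with the
#' referenced state's death probability:
#'
#' * `"direct"` — the value is the transition itself (default);
#' * `"excess_rate"` — additive on the hazard scale: the background death
#'   probability is converted to a rate, the excess rate added, and the sum
#'   converted back (the package default for disease-state mortality, since
#'   added hazards always yield valid probabilities);
#' * `"excess_rate_ratio"` — the background death rate is multiplied by the
#'   value (a hazard ratio);
#' * `"excess_prob"` — additive on the probability scale.
#'
#' @param from,to State ids.
#' @param value Probability in `[0,1]`, rate `>= 0`, or hazard ratio,
#'   depending on `scale`/`type`. May be `NA` when `age_dependent`.
#' @param scale `"probability"` or `"rate"`.
#' @param type Composition rule, see Details.
#' @param relative_to For excess types: id of the state whose
#'   transition-to-death supplies the background mortality.
#' @param age_dependent Logical; when `TRUE` the per-cycle probability is
#'   looked up from a life table at the cohort's current age instead of
#'   using `value`.
#' @return A one-row tibble; bind rows to form the transition table.
#' @export
transition <- function(from, to, value = NA_real_,
                       scale = c("probability", "rate"),
                       type = c("direct", "excess_rate", "excess_rate_ratio",
                                "excess_prob"),
                       relative_to = NA_character_,
                       age_dependent = FALSE) {
  scale <- match.arg(scale)
  type <- match.arg(type)
  tibble::tibble(
    from = from, to = to, value = as.numeric(value), scale = scale,
    type = type, relative_to = relative_to,
    age_dependent = isTRUE(age_dependent)
  )
}

#' Per-state utility and cost values
#'
#' Each alive state carries a health-related quality-of-life utility weight
#' (QALY weight per year, 0 = dead, 1 = full health) and two annual cost
#' aggregates: healthcare costs and societal costs (social care plus
#' patient-borne costs). The absorbing state must have utility 0 and zero
#' costs.
#'
#' @param state State id.
#' @param utility QALY weight per year.
#' @param cost_healthcare,cost_societal Annual costs, `>= 0`, in the
#'   analysis currency.
#' @return A one-row tibble; bind rows to form the state-value table.
#' @export
state_values <- function(state, utility, cost_healthcare = 0,
                         cost_societal = 0) {
  tibble::tibble(
    state = state, utility = as.numeric(utility),
    cost_healthcare = as.numeric(cost_healthcare),
    cost_societal = as.numeric(cost_societal)
  )
}

#' Assemble a Markov cohort model specification
#'
#' Combines states, transitions, state values and simulation settings into
#' a validated `model_spec` object describing one decision arm. The engine
#' accepts any number of states `>= 2` with exactly one absorbing state;
#' [three_state_spec()] builds the canonical baseline / deteriorated /
#' death model.
#'
#' @param states Tibble of [health_state()] rows.
#' @param transitions Tibble of [transition()] rows.
#' @param values Tibble of [state_values()] rows, one per state.
#' @param start_distribution Numeric occupancy vector over states, entries
#'   `>= 0` summing to 1. Defaults to the whole cohort in the first state.
#' @param cycle_length Years per cycle, `> 0`. Default 1.
#' @param start_age Cohort age in years at cycle 0, used for life-table
#'   lookups. Default 70.
#' @return An object of class `model_spec`.
#' @examples
#' spec <- three_state_spec(incidence = 0.1, recovery = 0.05,
#'                          mortality = 0.01, excess_mortality = 0.02)
#' spec
#' @export
model_spec <- function(states, transitions, values,
                       start_distribution = NULL,
                       cycle_length = 1, start_age = 70) {
  if (is.null(start_distribution)) {
    start_distribution <- c(1, rep(0, nrow(states) - 1L))
  }
  spec <- structure(
    list(
      states = tibble::as_tibble(states),
      transitions = tibble::as_tibble(transitions),
      values = tibble::as_tibble(values),
      start_distribution = as.numeric(start_distribution),
      cycle_length = cycle_length,
      start_age = start_age
    ),
    class = "model_spec"
  )
  validate_model_spec(spec)
  spec
}

#' Validate a model specification
#'
#' Checks every structural invariant: unique state ids, exactly one
#' absorbing state, no exits from the absorbing state, transition values in
#' domain, state values covering all states with a zero-valued absorbing
#' state, and a start distribution that is non-negative and sums to 1
#' (tolerance 1e-9). Residual self-transition feasibility is checked at
#' matrix-build time because it can depend on age.
#'
#' @param spec A `model_spec`.
#' @return `spec`, invisibly; errors describe the first violation found.
#' @export
validate_model_spec <- function(spec) {
  st <- spec$states
  tr <- spec$transitions
  if (nrow(st) < 2L) stop("a model needs at least 2 states.", call. = FALSE)
  if (anyDuplicated(st$id)) {
    stop("state ids must be unique; duplicated: ",
         paste(unique(st$id[duplicated(st$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (sum(st$absorbing) != 1L) {
    stop("exactly one state must be absorbing (death); found ",
         sum(st$absorbing), ".", call. = FALSE)
  }
  absorbing_id <- st$id[st$absorbing]
  unknown <- setdiff(c(tr$from, tr$to), st$id)
  if (length(unknown)) {
    stop("transition references undeclared state(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (any(tr$from == absorbing_id)) {
    stop("no transitions may leave the absorbing state '", absorbing_id, "'.",
         call. = FALSE)
  }
  bad_rel <- tr$type != "direct" & (is.na(tr$relative_to) |
                                      !tr$relative_to %in% st$id)
  if (any(bad_rel)) {
    stop("excess-mortality transitions must name a valid `relative_to` state.",
         call. = FALSE)
  }
  fixed <- !tr$age_dependent
  if (any(fixed & !is.finite(tr$value))) {
    stop("non-age-dependent transitions need a finite `value`.", call. = FALSE)
  }
  p_like <- fixed & tr$scale == "probability" & tr$type != "excess_rate_ratio"
  if (any(p_like & (tr$value < 0 | tr$value > 1))) {
    stop("probability-scale transition values must lie in [0, 1].",
         call. = FALSE)
  }
  if (any(fixed & tr$scale == "rate" & tr$value < 0)) {
    stop("rate-scale transition values must be >= 0.", call. = FALSE)
  }
  sv <- spec$values
  if (!setequal(sv$state, st$id) || nrow(sv) != nrow(st)) {
    stop("`values` must contain exactly one row per declared state.",
         call. = FALSE)
  }
  if (any(sv$cost_healthcare < 0) || any(sv$cost_societal < 0)) {
    stop("state costs must be >= 0.", call. = FALSE)
  }
  dead <- sv[sv$state == absorbing_id, ]
  if (dead$utility != 0 || dead$cost_healthcare != 0 || dead$cost_societal != 0) {
    stop("the absorbing state must have utility 0 and costs 0.", call. = FALSE)
  }
  sd0 <- spec$start_distribution
  if (length(sd0) != nrow(st) || any(sd0 < 0) || abs(sum(sd0) - 1) > 1e-9) {
    stop("`start_distribution` must be non-negative over all states and sum ",
         "to 1 (tolerance 1e-9).", call. = FALSE)
  }
  if (!is.numeric(spec$cycle_length) || spec$cycle_length <= 0) {
    stop("`cycle_length` must be > 0 years.", call. = FALSE)
  }
  invisible(spec)
}

#' Canonical three-state model: baseline health, deteriorated health, death
#'
#' Convenience constructor for the standard early-assessment model with
#' states `baseline`, `deteriorated` and `dead` and four transitions:
#' disease incidence (baseline to deteriorated), recovery (back), baseline
#' mortality, and mortality in the deteriorated state expressed as an
#' excess over baseline mortality.
#'
#' @param incidence Per-cycle probability of developing the deteriorated
#'   condition (or a rate, see `incidence_scale`).
#' @param recovery Per-cycle probability (or rate) of recovery back to
#'   baseline health.
#' @param mortality Annual baseline death probability; pass `NULL` to bind
#'   baseline mortality to a life table at run time (age-dependent).
#' @param excess_mortality Extra death hazard in the deteriorated state.
#'   Interpreted per `excess_scale`.
#' @param excess_scale `"rate"` (additive hazard per year, default),
#'   `"rate_ratio"` (hazard ratio applied to baseline mortality) or
#'   `"prob"` (additive per-cycle probability).
#' @param incidence_scale,recovery_scale `"probability"` or `"rate"`.
#' @param utilities Named vector with entries `baseline`, `deteriorated`.
#' @param costs_healthcare,costs_societal Named annual-cost vectors with
#'   entries `baseline`, `deteriorated`.
#' @param start_distribution Occupancy at cycle 0; default everyone in
#'   baseline health.
#' @param cycle_length Years per cycle. @param start_age Cohort start age.
#' @return A validated `model_spec`.
#' @export
three_state_spec <- function(incidence, recovery,
                             mortality = 0.01, excess_mortality = 0,
                             excess_scale = c("rate", "rate_ratio", "prob"),
                             incidence_scale = "probability",
                             recovery_scale = "probability",
                             utilities = c(baseline = 0.85, deteriorated = 0.6),
                             costs_healthcare = c(baseline = 0, deteriorated = 0),
                             costs_societal = c(baseline = 0, deteriorated = 0),
                             start_distribution = c(1, 0, 0),
                             cycle_length = 1, start_age = 70) {
  excess_scale <- match.arg(excess_scale)
  excess_type <- switch(excess_scale,
    rate = "excess_rate", rate_ratio = "excess_rate_ratio",
    prob = "excess_prob")
  excess_value_scale <- switch(excess_scale,
    rate = "rate", rate_ratio = "probability", prob = "probability")
  states <- dplyr::bind_rows(
    health_state("baseline", "baseline health"),
    health_state("deteriorated", "deteriorated health"),
    health_state("dead", "death", absorbing = TRUE)
  )
  age_dep <- is.null(mortality)
  transitions <- dplyr::bind_rows(
    transition("baseline", "deteriorated", incidence, incidence_scale),
    transition("deteriorated", "baseline", recovery, recovery_scale),
    transition("baseline", "dead",
               if (age_dep) NA_real_ else mortality,
               "probability", age_dependent = age_dep),
    transition("deteriorated", "dead", excess_mortality,
               scale = excess_value_scale, type = excess_type,
               relative_to = "baseline",
               age_dependent = FALSE)
  )
  values <- dplyr::bind_rows(
    state_values("baseline", utilities[["baseline"]],
                 costs_healthcare[["baseline"]], costs_societal[["baseline"]]),
    state_values("deteriorated", utilities[["deteriorated"]],
                 costs_healthcare[["deteriorated"]],
                 costs_societal[["deteriorated"]]),
    state_values("dead", 0, 0, 0)
  )
  model_spec(states, transitions, values, start_distribution,
             cycle_length, start_age)
}

#' @export
print.model_spec <- function(x, ...) {
  absorbing <- x$states$id[x$states$absorbing]
  cat("<model_spec> ", nrow(x$states), " states (absorbing: ", absorbing,
      "), ", nrow(x$transitions), " transitions, cycle ", x$cycle_length,
      " yr, start age ", x$start_age, "\n", sep = "")
  print(x$transitions, ...)
  invisible(x)
}
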
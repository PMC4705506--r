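#' Build the model specification for one decision arm
#'
#' Translates the shared state space plus one arm's transitions and state
#' values of a [parameter set][as_parameter_set] into a `model_spec`
#' ready for [run_cohort_trace()].
#'
#' @param ps A `parameter_set`.
#' @param arm `"control"` or `"intervention"`.
#' @return A validated `model_spec`.
#' @export
build_arm_spec <- function(ps, arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  a <- ps$arms[[arm]]
  # column-wise construction: this runs once per PSA draw per arm
  chr_field <- function(xs, f, default) {
    vapply(xs, function(x) as.character(x[[f]] %||% default), "")
  }
  num_field <- function(xs, f, default) {
    vapply(xs, function(x) as.numeric(x[[f]] %||% default), 0)
  }
  lgl_field <- function(xs, f) vapply(xs, function(x) isTRUE(x[[f]]), NA)
  ss <- ps$model$states
  states <- tibble::new_tibble(list(
    id = chr_field(ss, "id", NA_character_),
    label = vapply(ss, function(s) as.character(s$label %||% s$id), ""),
    absorbing = lgl_field(ss, "absorbing")
  ), nrow = length(ss))
  trs <- a$transitions
  transitions <- tibble::new_tibble(list(
    from = chr_field(trs, "from", NA_character_),
    to = chr_field(trs, "to", NA_character_),
    value = num_field(trs, "value", NA_real_),
    scale = chr_field(trs, "scale", "probability"),
    type = chr_field(trs, "type", "direct"),
    relative_to = chr_field(trs, "relative_to", NA_character_),
    age_dependent = lgl_field(trs, "age_dependent")
  ), nrow = length(trs))
  svs <- a$state_values
  values <- tibble::new_tibble(list(
    state = names(svs),
    utility = num_field(svs, "utility", NA_real_),
    cost_healthcare = num_field(svs, "cost_healthcare", 0),
    cost_societal = num_field(svs, "cost_societal", 0)
  ), nrow = length(svs))
  model_spec(states, transitions, values,
             start_distribution = ps$model$start_distribution,
             cycle_length = ps$model$cycle_length %||% 1,
             start_age = ps$model$start_age %||% 70)
}

# Settings precedence: explicit argument > ps$settings block > defaults.
resolve_settings <- function(ps, settings = NULL) {
  if (!is.null(settings)) {
    stopifnot(inherits(settings, "outcome_settings"))
    return(settings)
  }
  s <- ps$settings %||% list()
  if (!is.null(s$utility_bounds)) {
    s$utility_bounds <- as.numeric(unlist(s$utility_bounds))
  }
  do.call(outcome_settings, s)
}

ps_delivery_cost <- function(ps) {
  ic <- ps$intervention_cost
  if (is.null(ic)) return(NULL)
  intervention_cost(ic$one_off %||% 0, ic$per_cycle %||% 0)
}

#' Run the deterministic base-case comparison
#'
#' Simulates both arms of a parameter set over the configured horizon,
#' accumulates discounted QALYs and costs per arm, and summarises the
#' incremental result (delta E, delta C, ICER, INMB, dominance).
#'
#' @param ps A `parameter_set`.
#' @param settings Optional [outcome_settings()]; when omitted, the set's
#'   own `settings` block (or package defaults) apply.
#' @param life_table Optional [life_table()], required for age-dependent
#'   baseline mortality.
#' @return A `cea_result` holding both traces, both `arm_outcome`s and
#'   the `incremental_result`. Use [tidy()] for a per-arm tibble and
#'   [glance()] for the one-row incremental summary.
#' @examples
#' fx <- synthetic_fixture(42)
#' res <- run_comparison(fx$parameter_set, life_table = fx$life_table)
#' glance(res)
#' @export
run_comparison <- function(ps, settings = NULL, life_table = NULL) {
  ps <- as_parameter_set(ps)
  settings <- resolve_settings(ps, settings)
  traces <- list()
  arms <- list()
  for (arm in c("control", "intervention")) {
    spec <- build_arm_spec(ps, arm)
    traces[[arm]] <- run_cohort_trace(spec, settings$horizon_cycles,
                                      life_table)
    arms[[arm]] <- accumulate_arm(traces[[arm]], spec$values, settings)
  }
  inc <- incremental(arms$intervention, arms$control, settings,
                     delivery_cost = ps_delivery_cost(ps),
                     cycle_length = ps$model$cycle_length %||% 1)
  structure(
    list(parameter_set = ps, settings = settings, traces = traces,
         arms = arms, incremental = inc),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> horizon ", x$settings$horizon_cycles, " cycles, ",
      x$settings$perspective, " perspective\n", sep = "")
  for (arm in names(x$arms)) {
    cat("  ", format(arm, width = 12), ": ", sep = "")
    print(x$arms[[arm]])
  }
  print(x$incremental)
  invisible(x)
}

#' @export
#' @method tidy cea_result
tidy.cea_result <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$arms, function(a, arm) {
    dplyr::bind_cols(tibble::tibble(arm = arm), tidy(a))
  }))
}

#' @export
#' @method glance cea_result
glance.cea_result <- function(x, ...) {
  tidy(x$incremental)
}

#' @export
#' @method autoplot cea_result
autoplot.cea_result <- function(object, ...) {
  ids <- attr(object$traces$control, "states")$id
  long <- dplyr::bind_rows(purrr::imap(object$traces, function(tr, arm) {
    dplyr::mutate(
      tidyr::pivot_longer(tibble::as_tibble(tr),
                          cols = dplyr::all_of(ids),
                          names_to = "state", values_to = "occupancy"),
      arm = arm)
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "cycle", y = "proportion of cohort", colour = NULL) +
    ggplot2::theme_minimal()
}
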
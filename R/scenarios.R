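#' Define a deterministic scenario
#'
#' A scenario is a named set of parameter overrides applied on top of the
#' base case and re-evaluated deterministically. Override names are
#' dot-separated paths into the parameter set (e.g.
#' `"arms.intervention.transitions.incidence.value"`); paths starting
#' with `"settings."` override the analysis settings instead (e.g.
#' `"settings.lambda"`).
#'
#' @param name Scenario label.
#' @param overrides Named list mapping paths to replacement values.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("cheaper delivery",
#'               list(intervention_cost.one_off = 100))
#' @export
scenario_spec <- function(name, overrides = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.list(overrides))
  if (length(overrides) && is.null(names(overrides))) {
    stop("`overrides` must be a named list of path = value.", call. = FALSE)
  }
  structure(list(name = name, overrides = overrides),
            class = "scenario_spec")
}

apply_scenario <- function(ps, settings, scenario) {
  for (path in names(scenario$overrides)) {
    value <- scenario$overrides[[path]]
    if (startsWith(path, "settings.")) {
      field <- sub("^settings\\.", "", path)
      if (!field %in% names(settings)) {
        stop("scenario '", scenario$name, "': unknown settings field '",
             field, "'.", call. = FALSE)
      }
      settings[[field]] <- value
    } else {
      if (!has_path(ps, path)) {
        stop("scenario '", scenario$name, "': override path '", path,
             "' does not resolve.", call. = FALSE)
      }
      ps <- set_path(ps, path, value)
    }
  }
  list(ps = ps, settings = settings)
}

#' Deterministic scenario analysis
#'
#' Re-evaluates the comparison under each scenario's overrides in turn.
#' The unmodified base case is always included as the first row, so a
#' scenario table can be read as departures from it.
#'
#' @param ps A `parameter_set`.
#' @param scenarios List of [scenario_spec()]s.
#' @param settings Optional [outcome_settings()].
#' @param life_table Optional [life_table()].
#' @return A tibble with one row per scenario (base case first), columns
#'   `scenario`, `delta_e`, `delta_c`, `icer`, `inmb`, `dominance`,
#'   `lambda`, in the order given.
#' @export
run_scenarios <- function(ps, scenarios, settings = NULL,
                          life_table = NULL) {
  ps <- as_parameter_set(ps)
  settings <- resolve_settings(ps, settings)
  scenarios <- c(list(scenario_spec("base_case")), scenarios)
  rows <- purrr::map(scenarios, function(sc) {
    stopifnot(inherits(sc, "scenario_spec"))
    mod <- apply_scenario(ps, settings, sc)
    res <- run_comparison(mod$ps, mod$settings, life_table)
    dplyr::bind_cols(tibble::tibble(scenario = sc$name),
                     tidy(res$incremental))
  })
  dplyr::bind_rows(rows)
}

# Valid domain for a parameter path, used to clamp tornado percentiles.
target_domain <- function(ps, path, utility_bounds = c(0, 1)) {
  keys <- split_path(path)
  leaf <- keys[length(keys)]
  if (leaf == "utility") return(utility_bounds)
  if (leaf %in% c("cost_healthcare", "cost_societal", "one_off",
                  "per_cycle")) {
    return(c(0, Inf))
  }
  if ("transitions" %in% keys && leaf == "value") {
    tr <- get_path(ps, paste(keys[-length(keys)], collapse = "."))
    scale <- tr$scale %||% "probability"
    type <- tr$type %||% "direct"
    if (scale == "rate" || type == "excess_rate_ratio") return(c(0, Inf))
    return(c(0, 1))
  }
  c(-Inf, Inf)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Pivots each uncertain parameter alone to its low (2.5th percentile)
#' and high (97.5th percentile) value — or +/-20% around a fixed value —
#' while holding all other parameters at base, and records the INMB at
#' each extreme. Percentiles falling outside the parameter's valid
#' domain (e.g. a probability above 1) are clamped to the domain with a
#' warning. Rows are sorted by the width of the INMB excursion, the
#' conventional tornado ordering.
#'
#' @param ps A `parameter_set`.
#' @param distributions Optional list of [param_dist()]; defaults to the
#'   set's own `distributions` block.
#' @param settings Optional [outcome_settings()].
#' @param life_table Optional [life_table()].
#' @return A `tornado_result` tibble with columns `parameter`, `low`,
#'   `high`, `inmb_low`, `inmb_high`, `inmb_base`, `range`, sorted by
#'   `range` descending.
#' @export
one_way_tornado <- function(ps, distributions = NULL, settings = NULL,
                            life_table = NULL) {
  ps <- as_parameter_set(ps)
  settings <- resolve_settings(ps, settings)
  if (is.null(distributions)) {
    distributions <- purrr::map(ps$distributions, dist_from_json)
  }
  if (!length(distributions)) {
    stop("no parameter distributions to pivot.", call. = FALSE)
  }
  base <- run_comparison(ps, settings, life_table)
  inmb_base <- base$incremental$inmb
  rows <- purrr::map(distributions, function(d) {
    if (!has_path(ps, d$target)) {
      stop("distribution target '", d$target, "' does not resolve.",
           call. = FALSE)
    }
    q <- if (d$family == "fixed") {
      get_path(ps, d$target) * c(0.8, 1.2)
    } else {
      param_quantiles(d)
    }
    dom <- target_domain(ps, d$target, settings$utility_bounds)
    clamped <- q < dom[1] | q > dom[2]
    if (any(clamped)) {
      warning("tornado: percentile(s) for '", d$target,
              "' clamped to the valid domain [", dom[1], ", ", dom[2], "].",
              call. = FALSE)
      q <- pmin(pmax(q, dom[1]), dom[2])
    }
    inmb_at <- vapply(q, function(v) {
      run_comparison(set_path(ps, d$target, v), settings,
                     life_table)$incremental$inmb
    }, numeric(1))
    tibble::tibble(parameter = d$target, low = q[1], high = q[2],
                   inmb_low = inmb_at[1], inmb_high = inmb_at[2],
                   inmb_base = inmb_base,
                   range = abs(inmb_at[2] - inmb_at[1]))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$range))
  class(out) <- c("tornado_result", class(out))
  out
}

#' @export
#' @method autoplot tornado_result
autoplot.tornado_result <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    parameter = factor(.data$parameter, levels = rev(.data$parameter)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inmb_low,
                                       xend = .data$inmb_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$inmb_base),
                        linetype = "dashed") +
    ggplot2::labs(x = "INMB", y = NULL, title = "One-way sensitivity") +
    ggplot2::theme_minimal()
}
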
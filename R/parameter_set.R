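#' Parameter sets: the model inputs for both decision arms
#'
#' A `parameter_set` bundles everything needed to evaluate one
#' intervention against standard care: the shared state space and cohort
#' settings, per-arm transitions and state values, the intervention
#' delivery cost, optional analysis settings, and optional sampling
#' distributions for probabilistic sensitivity analysis. On disk it is a
#' strict, versioned JSON document; [read_parameter_set()] /
#' [write_parameter_set()] round-trip it.
#'
#' Default values for a population are expected to come from a curated
#' database; users replace individual values with local data via
#' [merge_overrides()], which tags every replaced leaf as
#' `user_provided`.
#'
#' @param x A nested list following the documented schema (as produced by
#'   [synthetic_fixture()] or read from JSON).
#' @return A validated object of class `parameter_set`.
#' @export
as_parameter_set <- function(x) {
  if (inherits(x, "parameter_set")) return(x)
  stopifnot(is.list(x))
  if (!is.null(x$model$start_distribution)) {
    x$model$start_distribution <- as.numeric(unlist(x$model$start_distribution))
  }
  if (!is.null(x$provenance)) {
    x$provenance <- as.character(unlist(x$provenance))
  }
  ps <- structure(x, class = "parameter_set")
  report <- validate_parameter_set(ps)
  stop_on_errors(report, "parameter set")
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> schema v", x$schema_version, " | population: ",
      x$metadata$population %||% "?", " | condition: ",
      x$metadata$condition %||% "?", "\n", sep = "")
  cat("  states: ", paste(vapply(x$model$states, `[[`, "", "id"),
                          collapse = ", "), "\n", sep = "")
  cat("  provenance: ", x$metadata$provenance %||% "default",
      if (length(x$provenance)) paste0(" (", length(x$provenance),
                                       " user-provided leaves)"), "\n",
      sep = "")
  cat("  distributions: ", length(x$distributions) %||% 0, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

schema_allowed <- list(
  top = c("schema_version", "metadata", "model", "arms", "intervention_cost",
          "settings", "distributions", "provenance"),
  metadata = c("population", "condition", "currency", "source", "provenance"),
  model = c("states", "start_distribution", "cycle_length", "start_age"),
  state = c("id", "label", "absorbing"),
  arm = c("transitions", "state_values"),
  transition = c("from", "to", "value", "scale", "type", "relative_to",
                 "age_dependent"),
  state_value = c("utility", "cost_healthcare", "cost_societal"),
  intervention_cost = c("one_off", "per_cycle"),
  settings = c("discount_rate_effects", "discount_rate_costs", "lambda",
               "perspective", "half_cycle_correction", "horizon_cycles",
               "utility_bounds", "currency"),
  distribution = c("target", "family", "mean", "se", "alpha", "beta",
                   "shape", "scale", "meanlog", "sdlog", "sd", "value",
                   "truncation")
)

#' Validate a parameter set
#'
#' Runs every machine-checkable rule against a parameter set and returns
#' a report instead of failing at the first problem: strict-schema checks
#' (unknown keys are rejected), domain checks (probabilities in `[0, 1]`,
#' utilities within bounds, non-negative costs, a zero-valued absorbing
#' state), referential checks (transitions must name declared states),
#' distribution feasibility, and a dry-run of the transition-matrix
#' builder to catch competing exit probabilities exceeding 1. A set with
#' an empty error list is loadable by the engine; warnings (e.g. an
#' intervention arm identical to control) do not block loading.
#'
#' @param ps A `parameter_set` or plain list following the schema.
#' @param life_table Optional [life_table()], needed to dry-run
#'   age-dependent mortality.
#' @param utility_bounds Admissible utility range.
#' @return A `validation_report`: a tibble with columns `severity`
#'   (`"error"`/`"warning"`), `path`, `message`.
#' @export
validate_parameter_set <- function(ps, life_table = NULL,
                                   utility_bounds = c(0, 1)) {
  entries <- list()
  note <- function(severity, path, message) {
    entries[[length(entries) + 1L]] <<-
      tibble::tibble(severity = severity, path = path, message = message)
  }
  check_keys <- function(x, allowed, path) {
    extra <- setdiff(names(x), allowed)
    for (k in extra) {
      note("error", paste0(path, k), "unknown key (strict schema)")
    }
  }

  check_keys(ps, schema_allowed$top, "")
  if (is.null(ps$schema_version)) {
    note("error", "schema_version", "missing")
  } else if (ps$schema_version != 1) {
    note("error", "schema_version",
         paste0("unsupported schema version ", ps$schema_version))
  }
  if (is.null(ps$metadata)) {
    note("error", "metadata", "missing")
  } else {
    check_keys(ps$metadata, schema_allowed$metadata, "metadata.")
    prov <- ps$metadata$provenance
    if (is.null(prov) || !prov %in% c("default", "user_provided")) {
      note("error", "metadata.provenance",
           "must be 'default' or 'user_provided'")
    }
  }

  states <- list()
  if (is.null(ps$model)) {
    note("error", "model", "missing")
  } else {
    check_keys(ps$model, schema_allowed$model, "model.")
    states <- ps$model$states %||% list()
    for (i in seq_along(states)) {
      check_keys(states[[i]], schema_allowed$state,
                 paste0("model.states.", i, "."))
    }
    ids <- vapply(states, function(s) s$id %||% "", "")
    if (length(states) < 2L) {
      note("error", "model.states", "at least 2 states are required")
    }
    if (anyDuplicated(ids)) note("error", "model.states", "duplicate ids")
    n_abs <- sum(vapply(states, function(s) isTRUE(s$absorbing), NA))
    if (n_abs != 1L) {
      note("error", "model.states",
           paste0("exactly one absorbing state required, found ", n_abs))
    }
    sd0 <- ps$model$start_distribution
    if (is.null(sd0) || length(sd0) != length(states) || any(sd0 < 0) ||
        abs(sum(sd0) - 1) > 1e-9) {
      note("error", "model.start_distribution",
           "must be non-negative over all states and sum to 1")
    }
    if (is.null(ps$model$cycle_length) || ps$model$cycle_length <= 0) {
      note("error", "model.cycle_length", "must be > 0 years")
    }
    if (is.null(ps$model$start_age) || ps$model$start_age < 0) {
      note("error", "model.start_age", "must be >= 0")
    }
  }
  ids <- vapply(states, function(s) s$id %||% "", "")
  absorbing_id <- ids[vapply(states, function(s) isTRUE(s$absorbing), NA)]

  if (is.null(ps$arms) || !setequal(names(ps$arms),
                                    c("control", "intervention"))) {
    note("error", "arms", "must contain exactly 'control' and 'intervention'")
  } else {
    for (arm_name in c("control", "intervention")) {
      arm <- ps$arms[[arm_name]]
      apath <- paste0("arms.", arm_name, ".")
      check_keys(arm, schema_allowed$arm, apath)
      trs <- arm$transitions %||% list()
      for (tn in names(trs)) {
        tr <- trs[[tn]]
        tpath <- paste0(apath, "transitions.", tn)
        check_keys(tr, schema_allowed$transition, paste0(tpath, "."))
        for (ref in c("from", "to")) {
          if (!is.null(tr[[ref]]) && !tr[[ref]] %in% ids) {
            note("error", paste0(tpath, ".", ref),
                 paste0("references undeclared state '", tr[[ref]], "'"))
          }
        }
        if (length(absorbing_id) == 1L && identical(tr$from, absorbing_id)) {
          note("error", paste0(tpath, ".from"),
               "transitions may not leave the absorbing state")
        }
        scale <- tr$scale %||% "probability"
        type <- tr$type %||% "direct"
        if (!scale %in% c("probability", "rate")) {
          note("error", paste0(tpath, ".scale"), "must be probability|rate")
        }
        if (!type %in% c("direct", "excess_rate", "excess_rate_ratio",
                         "excess_prob")) {
          note("error", paste0(tpath, ".type"), "unknown composition type")
        }
        if (type != "direct" &&
            (is.null(tr$relative_to) || !tr$relative_to %in% ids)) {
          note("error", paste0(tpath, ".relative_to"),
               "excess transitions must reference a declared state")
        }
        if (!isTRUE(tr$age_dependent)) {
          v <- tr$value
          if (is.null(v) || !is.finite(v)) {
            note("error", paste0(tpath, ".value"),
                 "a finite value is required unless age_dependent")
          } else if (scale == "probability" && type != "excess_rate_ratio" &&
                     (v < 0 || v > 1)) {
            note("error", paste0(tpath, ".value"),
                 paste0("probability ", v, " outside [0, 1]"))
          } else if (scale == "rate" && v < 0) {
            note("error", paste0(tpath, ".value"), "rate must be >= 0")
          }
        }
      }
      svs <- arm$state_values %||% list()
      missing_sv <- setdiff(ids, names(svs))
      if (length(missing_sv)) {
        note("error", paste0(apath, "state_values"),
             paste0("missing state(s): ", paste(missing_sv, collapse = ", ")))
      }
      for (sn in names(svs)) {
        sv <- svs[[sn]]
        spath <- paste0(apath, "state_values.", sn)
        check_keys(sv, schema_allowed$state_value, paste0(spath, "."))
        if (!sn %in% ids) {
          note("error", spath, paste0("values for undeclared state '", sn, "'"))
          next
        }
        u <- sv$utility %||% NA_real_
        if (!is.finite(u) || u < utility_bounds[1] || u > utility_bounds[2]) {
          note("error", paste0(spath, ".utility"),
               paste0("utility ", u, " outside [", utility_bounds[1], ", ",
                      utility_bounds[2], "]"))
        }
        for (cn in c("cost_healthcare", "cost_societal")) {
          cv <- sv[[cn]] %||% NA_real_
          if (!is.finite(cv) || cv < 0) {
            note("error", paste0(spath, ".", cn), "must be >= 0")
          }
        }
        if (length(absorbing_id) == 1L && sn == absorbing_id) {
          if (!isTRUE(u == 0) || !isTRUE((sv$cost_healthcare %||% 0) == 0) ||
              !isTRUE((sv$cost_societal %||% 0) == 0)) {
            note("error", spath,
                 "the absorbing state must have utility 0 and costs 0")
          }
        }
      }
    }
    if (identical(ps$arms$control, ps$arms$intervention)) {
      note("warning", "arms",
           "intervention arm identical to control: zero incremental effect")
    }
  }

  if (!is.null(ps$intervention_cost)) {
    check_keys(ps$intervention_cost, schema_allowed$intervention_cost,
               "intervention_cost.")
    for (cn in c("one_off", "per_cycle")) {
      cv <- ps$intervention_cost[[cn]] %||% 0
      if (cv < 0) note("error", paste0("intervention_cost.", cn),
                       "must be >= 0")
    }
  }
  if (!is.null(ps$settings)) {
    check_keys(ps$settings, schema_allowed$settings, "settings.")
  }
  for (i in seq_along(ps$distributions)) {
    d <- ps$distributions[[i]]
    dpath <- paste0("distributions.", i)
    check_keys(d, schema_allowed$distribution, paste0(dpath, "."))
    if (is.null(d$target) || !has_path(ps, d$target)) {
      note("error", paste0(dpath, ".target"),
           paste0("target '", d$target %||% "<missing>",
                  "' does not resolve"))
      next
    }
    parsed <- tryCatch(dist_from_json(d), error = function(e) e)
    if (inherits(parsed, "error")) {
      note("error", dpath, conditionMessage(parsed))
    }
  }

  # dry-run: residual self-transition feasibility at cycle 0
  if (!any(vapply(entries, function(e) e$severity == "error", NA))) {
    for (arm_name in c("control", "intervention")) {
      res <- tryCatch({
        spec <- build_arm_spec(ps, arm_name)
        if (any(spec$transitions$age_dependent) && is.null(life_table)) {
          note("warning", paste0("arms.", arm_name),
               "age-dependent mortality: residual check needs a life table")
        } else {
          build_transition_matrix(spec, 0, life_table)
        }
        NULL
      }, error = function(e) e)
      if (inherits(res, "error")) {
        note("error", paste0("arms.", arm_name), conditionMessage(res))
      }
    }
  }

  report <- if (length(entries)) dplyr::bind_rows(entries) else {
    tibble::tibble(severity = character(), path = character(),
                   message = character())
  }
  class(report) <- c("validation_report", class(report))
  report
}

dist_from_json <- function(d) {
  nat <- d[intersect(names(d), c("alpha", "beta", "shape", "scale",
                                 "meanlog", "sdlog", "sd", "value"))]
  args <- c(list(target = d$target, family = d$family, mean = d$mean,
                 se = d$se,
                 truncation = if (!is.null(d$truncation))
                   as.numeric(unlist(d$truncation))),
            nat)
  do.call(param_dist, args[!vapply(args, is.null, NA)])
}

#' @export
print.validation_report <- function(x, ...) {
  n_err <- sum(x$severity == "error")
  n_warn <- sum(x$severity == "warning")
  cat("<validation_report> ", n_err, " errors, ", n_warn, " warnings\n",
      sep = "")
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$path[i], x$message[i]))
    }
  }
  invisible(x)
}

stop_on_errors <- function(report, what) {
  errs <- report[report$severity == "error", ]
  if (nrow(errs)) {
    msg <- paste0(what, " failed validation with ", nrow(errs), " error(s):\n",
                  paste0("  ", errs$path, ": ", errs$message, collapse = "\n"))
    cond <- structure(
      class = c("markovcea_validation_error", "error", "condition"),
      list(message = msg, call = NULL, report = report)
    )
    stop(cond)
  }
  invisible(report)
}

#' Read / write a parameter set as JSON
#'
#' `read_parameter_set()` parses and fully validates a JSON document; on
#' any error it raises a condition carrying the complete
#' `validation_report`. `write_parameter_set()` writes the canonical
#' pretty-printed form, which round-trips byte-identically.
#'
#' @param path JSON file path.
#' @return `read_parameter_set()` returns a `parameter_set`;
#'   `write_parameter_set()` returns `path` invisibly.
#' @export
read_parameter_set <- function(path) {
  if (!file.exists(path)) {
    stop("parameter set file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_parameter_set(raw)
}

#' @rdname read_parameter_set
#' @param ps A `parameter_set`.
#' @export
write_parameter_set <- function(ps, path) {
  x <- unclass(ps)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Merge user overrides into a default parameter set
#'
#' Deep-merges a partial override document on top of a default set;
#' overrides win. Every override leaf must resolve to an existing path in
#' the defaults (strict: no new keys can be introduced), and each
#' overridden leaf is re-tagged with `user_provided` provenance. The
#' merged set is re-validated; a set that no longer passes (e.g. an
#' override pushing competing exit probabilities above 1) raises the full
#' `validation_report`.
#'
#' @param defaults A `parameter_set`.
#' @param overrides Nested list mirroring part of the schema, or a path
#'   to a JSON file containing one.
#' @param life_table Optional life table for re-validation.
#' @return A validated `parameter_set` with updated `provenance`.
#' @examples
#' ps <- synthetic_fixture(1)$parameter_set
#' ps2 <- merge_overrides(ps, list(arms = list(control = list(
#'   state_values = list(baseline = list(utility = 0.9))))))
#' ps2$provenance
#' @export
merge_overrides <- function(defaults, overrides, life_table = NULL) {
  defaults <- as_parameter_set(defaults)
  if (is.character(overrides) && length(overrides) == 1L) {
    overrides <- jsonlite::read_json(overrides, simplifyVector = FALSE)
  }
  stopifnot(is.list(overrides))
  if (length(overrides) == 0L) return(defaults)
  paths <- leaf_paths(overrides)
  merged <- unclass(defaults)
  for (p in paths) {
    if (!has_path(merged, p)) {
      stop("override path '", p, "' does not resolve against the defaults.",
           call. = FALSE)
    }
    merged <- set_path(merged, p, get_path(overrides, p))
  }
  merged$provenance <- sort(union(merged$provenance %||% character(), paths))
  merged$metadata$provenance <- "user_provided"
  report <- validate_parameter_set(merged, life_table)
  stop_on_errors(report, "merged parameter set")
  structure(merged, class = "parameter_set")
}
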
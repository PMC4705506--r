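#' Build the per-cycle transition matrix
#'
#' Resolves every transition of a model to a per-cycle probability for a
#' given cycle: rates are converted with [rate_to_prob()], age-dependent
#' transitions are looked up from the life table at the cohort's age
#' `floor(start_age + cycle_index * cycle_length)`, and excess-mortality
#' transitions are composed with the referenced state's death probability
#' according to their `type` (see [transition()]). The diagonal is then
#' set to the residual so each row sums to exactly 1; a negative residual
#' (competing exits exceeding 1) is a hard error naming the state and
#' cycle, never a silent renormalisation.
#'
#' @param spec A `model_spec`.
#' @param cycle_index Cycle for which the matrix applies (0-based).
#' @param life_table Optional [life_table()]; required when any transition
#'   is age-dependent.
#' @return A square row-stochastic matrix with state ids as dimnames; the
#'   absorbing row is the identity row.
#' @examples
#' spec <- three_state_spec(0.1, 0.05, mortality = 0.01,
#'                          excess_mortality = 0.02, excess_scale = "prob")
#' build_transition_matrix(spec, 0)
#' @export
build_transition_matrix <- function(spec, cycle_index = 0, life_table = NULL) {
  build_matrix_ctx(matrix_ctx(spec), cycle_index, life_table)
}

# Hoist everything cycle-invariant out of the per-cycle builder; one ctx
# serves every cycle of a trace (and, in PSA, every draw rebuilds it once).
matrix_ctx <- function(spec) {
  list(
    ids = spec$states$id,
    absorbing = spec$states$id[spec$states$absorbing],
    cl = spec$cycle_length,
    start_age = spec$start_age,
    from = spec$transitions$from,
    to = spec$transitions$to,
    value = spec$transitions$value,
    scale = spec$transitions$scale,
    type = spec$transitions$type,
    rel = spec$transitions$relative_to,
    aged = spec$transitions$age_dependent
  )
}

build_matrix_ctx <- function(ctx, cycle_index, life_table = NULL) {
  ids <- ctx$ids
  n <- length(ids)
  cl <- ctx$cl
  age <- ctx$start_age + cycle_index * cl
  tr_from <- ctx$from
  tr_to <- ctx$to
  tr_value <- ctx$value
  tr_scale <- ctx$scale
  tr_type <- ctx$type
  tr_rel <- ctx$rel
  tr_aged <- ctx$aged

  # per-cycle probability of transition i, before composition
  base_prob <- function(i) {
    if (tr_aged[i]) {
      if (is.null(life_table)) {
        stop("transition ", tr_from[i], " -> ", tr_to[i],
             " is age-dependent but no life table was supplied.",
             call. = FALSE)
      }
      p_annual <- lookup_mortality(life_table, age)
      if (cl == 1) p_annual
      else if (p_annual >= 1) 1
      else rate_to_prob(prob_to_rate(p_annual, 1), cl)
    } else if (tr_scale[i] == "rate") {
      rate_to_prob(tr_value[i], cl)
    } else {
      tr_value[i]
    }
  }

  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in which(tr_type == "direct")) {
    M[tr_from[i], tr_to[i]] <- M[tr_from[i], tr_to[i]] + base_prob(i)
  }

  for (i in which(tr_type != "direct")) {
    p_ref <- M[tr_rel[i], tr_to[i]]
    # background probability 1 means an unbounded hazard: death is
    # certain whatever the excess
    p <- if (p_ref >= 1 && tr_type[i] != "excess_prob") 1 else switch(tr_type[i],
      excess_rate = {
        r <- prob_to_rate(p_ref, cl) + if (tr_scale[i] == "rate") tr_value[i]
                                       else prob_to_rate(tr_value[i], cl)
        rate_to_prob(r, cl)
      },
      excess_rate_ratio = rate_to_prob(prob_to_rate(p_ref, cl) * tr_value[i],
                                       cl),
      excess_prob = p_ref + base_prob(i)
    )
    if (p < 0 || p > 1) {
      stop("composed mortality for state '", tr_from[i], "' at cycle ",
           cycle_index, " is ", signif(p, 6), ", outside [0, 1].",
           call. = FALSE)
    }
    M[tr_from[i], tr_to[i]] <- M[tr_from[i], tr_to[i]] + p
  }

  absorbing <- ctx$absorbing
  for (s in ids) {
    if (s == absorbing) {
      M[s, ] <- 0
      M[s, s] <- 1
      next
    }
    exits <- sum(M[s, ]) - M[s, s]
    residual <- 1 - exits
    if (residual < -1e-12) {
      stop("exit probabilities from state '", s, "' sum to ",
           signif(exits, 6), " (> 1) at cycle ", cycle_index,
           "; the residual self-transition would be negative.",
           call. = FALSE)
    }
    M[s, s] <- max(residual, 0)
  }
  M
}

#' Simulate a cohort trace
#'
#' Propagates the start distribution through the per-cycle transition
#' matrices: row 0 is the start distribution and row `t+1` equals row `t`
#' times the cycle-`t` matrix. With no age-dependent transitions the chain
#' is time-homogeneous and the single matrix is built once.
#'
#' @param spec A `model_spec`.
#' @param horizon_cycles Number of cycles to simulate, `>= 1`.
#' @param life_table Optional [life_table()] for age-dependent mortality.
#' @return A `cohort_trace`: a tibble with columns `cycle`, `age`, and one
#'   occupancy column per state; rows sum to 1 and absorbing-state
#'   occupancy is non-decreasing. Attributes carry `cycle_length`,
#'   `start_age` and the state table. Use [trace_matrix()] for the bare
#'   occupancy matrix.
#' @examples
#' spec <- three_state_spec(0.1, 0.05, mortality = 0.01)
#' run_cohort_trace(spec, 5)
#' @export
run_cohort_trace <- function(spec, horizon_cycles, life_table = NULL) {
  validate_model_spec(spec)
  if (horizon_cycles < 1) stop("`horizon_cycles` must be >= 1.", call. = FALSE)
  ids <- spec$states$id
  n <- length(ids)
  occ <- matrix(NA_real_, horizon_cycles + 1L, n,
                dimnames = list(NULL, ids))
  occ[1L, ] <- spec$start_distribution
  homogeneous <- !any(spec$transitions$age_dependent)
  ctx <- matrix_ctx(spec)
  M <- build_matrix_ctx(ctx, 0, life_table)
  for (t in seq_len(horizon_cycles)) {
    if (!homogeneous && t > 1L) {
      M <- build_matrix_ctx(ctx, t - 1L, life_table)
    }
    occ[t + 1L, ] <- occ[t, , drop = TRUE] %*% M
  }
  cols <- c(
    list(cycle = 0:horizon_cycles,
         age = spec$start_age + (0:horizon_cycles) * spec$cycle_length),
    lapply(seq_along(ids), function(j) occ[, j])
  )
  names(cols)[-(1:2)] <- ids
  out <- tibble::new_tibble(cols, nrow = horizon_cycles + 1L)
  structure(out,
            class = c("cohort_trace", class(out)),
            states = spec$states,
            occupancy = occ,
            cycle_length = spec$cycle_length,
            start_age = spec$start_age)
}

#' Extract the occupancy matrix from a cohort trace
#'
#' @param trace A `cohort_trace`.
#' @return Numeric matrix, rows = cycles 0..T, columns = states.
#' @export
trace_matrix <- function(trace) {
  occ <- attr(trace, "occupancy")
  if (!is.null(occ)) return(occ)
  ids <- attr(trace, "states")$id
  as.matrix(as.data.frame(trace)[, ids, drop = FALSE])
}

#' Plot state occupancy over time
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot of occupancy proportion by cycle, one line per state.
#' @export
#' @method autoplot cohort_trace
autoplot.cohort_trace <- function(object, ...) {
  ids <- attr(object, "states")$id
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(ids),
                              names_to = "state", values_to = "occupancy")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "proportion of cohort", colour = NULL) +
    ggplot2::theme_minimal()
}
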
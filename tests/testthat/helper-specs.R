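# Random valid model specs and independent oracles shared across tests.

# A random N-state spec (last state absorbing) with exit probabilities
# scaled to keep every residual self-transition strictly positive, and a
# positive death exit from every alive state.
random_valid_spec <- function(n_states = sample(2:6, 1),
                              cycle_length = sample(c(0.5, 1), 1)) {
  ids <- c(paste0("s", seq_len(n_states - 1L)), "dead")
  states <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    health_state(ids[i], absorbing = i == length(ids))
  }))
  transitions <- dplyr::bind_rows(lapply(seq_len(n_states - 1L), function(i) {
    targets <- setdiff(ids, ids[i])
    p <- stats::runif(length(targets), 0.01, 1)
    p <- p / sum(p) * stats::runif(1, 0.1, 0.9)  # exits sum < 1
    dplyr::bind_rows(lapply(seq_along(targets), function(j) {
      transition(ids[i], targets[j], p[j], scale = "probability")
    }))
  }))
  values <- dplyr::bind_rows(lapply(ids, function(s) {
    if (s == "dead") state_values(s, 0, 0, 0)
    else state_values(s, stats::runif(1), stats::runif(1, 0, 5000),
                      stats::runif(1, 0, 3000))
  }))
  start <- stats::runif(n_states)
  start <- start / sum(start)
  model_spec(states, transitions, values, start_distribution = start,
             cycle_length = cycle_length, start_age = 60)
}

# Independent matrix-power oracle (exponentiation by squaring) for
# time-homogeneous chains: start %*% M^t.
mat_power <- function(M, t) {
  result <- diag(nrow(M))
  base <- M
  while (t > 0) {
    if (t %% 2 == 1) result <- result %*% base
    base <- base %*% base
    t <- t %/% 2
  }
  result
}

# A small self-contained parameter set (no age dependence) for PSA and
# scenario tests where life-table plumbing would only add noise.
make_test_ps <- function(incidence_int = 0.06, horizon = 10,
                         distributions = list()) {
  arm <- function(incidence) {
    list(
      transitions = list(
        incidence = list(from = "baseline", to = "deteriorated",
                         value = incidence, scale = "probability",
                         type = "direct"),
        recovery = list(from = "deteriorated", to = "baseline",
                        value = 0.05, scale = "probability",
                        type = "direct"),
        baseline_mortality = list(from = "baseline", to = "dead",
                                  value = 0.02, scale = "probability",
                                  type = "direct"),
        excess_mortality = list(from = "deteriorated", to = "dead",
                                value = 0.03, scale = "rate",
                                type = "excess_rate",
                                relative_to = "baseline")
      ),
      state_values = list(
        baseline = list(utility = 0.85, cost_healthcare = 1000,
                        cost_societal = 300),
        deteriorated = list(utility = 0.6, cost_healthcare = 4000,
                            cost_societal = 2000),
        dead = list(utility = 0, cost_healthcare = 0, cost_societal = 0)
      )
    )
  }
  as_parameter_set(list(
    schema_version = 1,
    metadata = list(population = "test", condition = "test",
                    currency = "EUR", source = "unit test",
                    provenance = "default"),
    model = list(
      states = list(
        list(id = "baseline", label = "baseline health", absorbing = FALSE),
        list(id = "deteriorated", label = "deteriorated health",
             absorbing = FALSE),
        list(id = "dead", label = "death", absorbing = TRUE)
      ),
      start_distribution = c(1, 0, 0),
      cycle_length = 1, start_age = 70
    ),
    arms = list(control = arm(0.10), intervention = arm(incidence_int)),
    intervention_cost = list(one_off = 200, per_cycle = 50),
    settings = list(horizon_cycles = horizon),
    distributions = distributions
  ))
}
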
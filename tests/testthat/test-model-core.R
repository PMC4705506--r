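test_that("transition matrix matches hand arithmetic for the 3-state model", {
  spec <- three_state_spec(incidence = 0.10, recovery = 0.05,
                           mortality = 0.01, excess_mortality = 0.02,
                           excess_scale = "prob")
  M <- build_transition_matrix(spec, 0)
  expect_equal(unname(M["baseline", ]), c(0.89, 0.10, 0.01))
  expect_equal(unname(M["deteriorated", ]), c(0.05, 0.92, 0.03))
  expect_equal(unname(M["dead", ]), c(0, 0, 1))
})

test_that("excess mortality composes on the hazard scale by default", {
  spec <- three_state_spec(0.1, 0.05, mortality = 0.01,
                           excess_mortality = 0.02, excess_scale = "rate")
  M <- build_transition_matrix(spec, 0)
  expected <- 1 - exp(-(-log(1 - 0.01) + 0.02))
  expect_equal(M["deteriorated", "dead"], expected, tolerance = 1e-14)

  spec_rr <- three_state_spec(0.1, 0.05, mortality = 0.01,
                              excess_mortality = 2,
                              excess_scale = "rate_ratio")
  M_rr <- build_transition_matrix(spec_rr, 0)
  expect_equal(M_rr["deteriorated", "dead"],
               1 - exp(2 * log(1 - 0.01)), tolerance = 1e-14)
})

test_that("all-zero transitions give the identity matrix", {
  spec <- three_state_spec(0, 0, mortality = 0, excess_mortality = 0)
  expect_equal(unname(build_transition_matrix(spec, 0)), diag(3))
})

test_that("competing exits above 1 are a hard error naming the state", {
  spec <- three_state_spec(incidence = 0.7, recovery = 0,
                           mortality = 0.5, excess_mortality = 0)
  expect_error(build_transition_matrix(spec, 0), "baseline.*cycle 0")
})

test_that("spec validation enforces structural invariants", {
  st <- dplyr::bind_rows(health_state("a"),
                         health_state("dead", absorbing = TRUE))
  tr <- transition("a", "dead", 0.1)
  sv <- dplyr::bind_rows(state_values("a", 0.8), state_values("dead", 0))
  expect_s3_class(model_spec(st, tr, sv), "model_spec")

  # two absorbing states
  st2 <- dplyr::bind_rows(health_state("a", absorbing = TRUE),
                          health_state("dead", absorbing = TRUE))
  expect_error(model_spec(st2, tr, sv), "absorbing")
  # dangling transition reference
  expect_error(model_spec(st, transition("a", "frail", 0.1), sv),
               "undeclared")
  # exit from the absorbing state
  expect_error(model_spec(st, dplyr::bind_rows(tr,
                          transition("dead", "a", 0.1)), sv), "absorbing")
  # probability out of range
  expect_error(model_spec(st, transition("a", "dead", 1.2), sv),
               "\\[0, 1\\]")
  # start distribution not summing to 1
  expect_error(model_spec(st, tr, sv, start_distribution = c(0.6, 0.6)),
               "sum")
  # non-zero values on the dead state
  sv_bad <- dplyr::bind_rows(state_values("a", 0.8),
                             state_values("dead", 0.1))
  expect_error(model_spec(st, tr, sv_bad), "absorbing state")
})

test_that("one cycle reproduces the hand-computed vector-matrix product", {
  spec <- three_state_spec(0.10, 0.05, mortality = 0.01,
                           excess_mortality = 0.02, excess_scale = "prob")
  tr <- run_cohort_trace(spec, 1)
  expect_equal(unname(trace_matrix(tr)[1, ]), c(1, 0, 0))
  expect_equal(unname(trace_matrix(tr)[2, ]), c(0.89, 0.10, 0.01))
})

test_that("identity dynamics leave the start distribution unchanged", {
  spec <- three_state_spec(0, 0, mortality = 0, excess_mortality = 0,
                           start_distribution = c(0.5, 0.3, 0.2))
  occ <- trace_matrix(run_cohort_trace(spec, 7))
  for (t in 1:8) expect_equal(unname(occ[t, ]), c(0.5, 0.3, 0.2))
})

test_that("iterative trace equals an independent matrix-power oracle", {
  set.seed(421)
  for (i in 1:20) {
    spec <- random_valid_spec()
    M <- build_transition_matrix(spec, 0)
    occ <- trace_matrix(run_cohort_trace(spec, 8))
    oracle <- spec$start_distribution %*% mat_power(M, 8)
    expect_equal(unname(occ[9, ]), unname(drop(oracle)), tolerance = 1e-12)
  }
})

test_that("trace rows conserve mass and death occupancy is monotone", {
  set.seed(99)
  for (i in 1:25) {
    spec <- random_valid_spec()
    occ <- trace_matrix(run_cohort_trace(spec, 20))
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(diff(occ[, "dead"]) >= -1e-12))
  }
})

test_that("death absorbs the whole cohort in the long run", {
  spec <- three_state_spec(0.1, 0.05, mortality = 0.02,
                           excess_mortality = 0.03)
  occ <- trace_matrix(run_cohort_trace(spec, 400))
  expect_gt(occ[401, "dead"], 1 - 1e-3)
})

test_that("survival matches the geometric closed form without disease", {
  for (m in c(0.01, 0.05, 0.1)) {
    spec <- three_state_spec(0, 0, mortality = m, excess_mortality = 0)
    occ <- trace_matrix(run_cohort_trace(spec, 25))
    person_cycles <- sum(occ[-1, "baseline"])
    expect_equal(person_cycles, sum((1 - m)^(1:25)), tolerance = 1e-9)
  }
})

test_that("age-dependent mortality follows the life table", {
  lt <- life_table(70:80, c(seq(0.02, 0.10, length.out = 10), 1),
                   population = "toy")
  spec <- three_state_spec(0, 0, mortality = NULL, excess_mortality = 0,
                           start_age = 70)
  M0 <- build_transition_matrix(spec, 0, lt)
  M5 <- build_transition_matrix(spec, 5, lt)
  expect_equal(M0["baseline", "dead"], lt$mortality_prob[1])
  expect_equal(M5["baseline", "dead"], lt$mortality_prob[6])
  expect_error(build_transition_matrix(spec, 0),
               "no life table")
  # a closed table (final probability 1) covers all later ages
  expect_equal(build_transition_matrix(spec, 30, lt)["baseline", "dead"], 1)
  young <- three_state_spec(0, 0, mortality = NULL, excess_mortality = 0,
                            start_age = 50)
  expect_error(build_transition_matrix(young, 0, lt), "does not cover")
})

test_that("life table validation enforces contiguity, domain and closure", {
  expect_error(life_table(c(70, 72), c(0.1, 1)), "contiguous")
  expect_error(life_table(70:71, c(1.5, 1)), "\\[0, 1\\]")
  expect_error(life_table(70:71, c(0.1, 0.2)), "probability 1")
  expect_s3_class(life_table(70:71, c(0.1, 0.2), open_ended = TRUE),
                  "life_table")
})
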
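settings_plain <- outcome_settings(discount_rate_effects = 0,
                                   discount_rate_costs = 0,
                                   half_cycle_correction = FALSE,
                                   horizon_cycles = 10)

test_that("a static cohort accrues utility x years and cost x years", {
  spec <- three_state_spec(0, 0, mortality = 0, excess_mortality = 0,
                           utilities = c(baseline = 0.8, deteriorated = 0.6),
                           costs_healthcare = c(baseline = 1000,
                                                deteriorated = 0))
  tr <- run_cohort_trace(spec, 10)
  out <- accumulate_arm(tr, spec$values, settings_plain)
  expect_equal(out$qalys, 8)
  expect_equal(out$cost_healthcare, 10000)
  expect_equal(out$life_years, 10)
})

test_that("QALYs under constant mortality match the geometric series", {
  spec <- three_state_spec(0, 0, mortality = 0.1, excess_mortality = 0,
                           utilities = c(baseline = 1, deteriorated = 1))
  tr <- run_cohort_trace(spec, 5)
  s <- outcome_settings(discount_rate_effects = 0, discount_rate_costs = 0,
                        half_cycle_correction = FALSE, horizon_cycles = 5)
  out <- accumulate_arm(tr, spec$values, s)
  expect_equal(out$qalys, sum(0.9^(1:5)), tolerance = 1e-12)
  expect_equal(out$qalys, out$life_years)
})

test_that("half-cycle correction averages adjacent occupancy rows", {
  spec <- three_state_spec(0, 0, mortality = 0.1, excess_mortality = 0,
                           utilities = c(baseline = 1, deteriorated = 1))
  tr <- run_cohort_trace(spec, 5)
  s_hcc <- outcome_settings(discount_rate_effects = 0,
                            discount_rate_costs = 0,
                            half_cycle_correction = TRUE,
                            horizon_cycles = 5)
  out <- accumulate_arm(tr, spec$values, s_hcc)
  surv <- 0.9^(0:5)
  expect_equal(out$qalys, sum((surv[-6] + surv[-1]) / 2), tolerance = 1e-12)
})

test_that("discounting never increases QALYs and is neutral at rate 0", {
  spec <- three_state_spec(0.1, 0.05, mortality = 0.02,
                           excess_mortality = 0.01)
  tr <- run_cohort_trace(spec, 15)
  s0 <- outcome_settings(discount_rate_effects = 0, discount_rate_costs = 0,
                         horizon_cycles = 15)
  s3 <- outcome_settings(discount_rate_effects = 0.03,
                         discount_rate_costs = 0.03, horizon_cycles = 15)
  q0 <- accumulate_arm(tr, spec$values, s0)$qalys
  q3 <- accumulate_arm(tr, spec$values, s3)$qalys
  expect_lt(q3, q0)
})

test_that("QALYs are bounded by discounted life years when utility <= 1", {
  set.seed(7)
  for (i in 1:10) {
    spec <- random_valid_spec()
    tr <- run_cohort_trace(spec, 12)
    out <- accumulate_arm(tr, spec$values,
                          outcome_settings(horizon_cycles = 12))
    expect_lte(out$qalys, out$life_years + 1e-12)
  }
})

test_that("perspective selects the cost total and societal nests healthcare", {
  spec <- three_state_spec(0.1, 0.05, mortality = 0.02,
                           costs_healthcare = c(baseline = 500,
                                                deteriorated = 3000),
                           costs_societal = c(baseline = 200,
                                              deteriorated = 1500))
  tr <- run_cohort_trace(spec, 10)
  hc <- accumulate_arm(tr, spec$values,
                       outcome_settings(perspective = "healthcare",
                                        horizon_cycles = 10))
  soc <- accumulate_arm(tr, spec$values,
                        outcome_settings(perspective = "societal",
                                         horizon_cycles = 10))
  expect_equal(hc$cost_total_for_perspective, hc$cost_healthcare)
  expect_equal(soc$cost_total_for_perspective,
               soc$cost_healthcare + soc$cost_societal)
  expect_gte(soc$cost_total_for_perspective,
             hc$cost_total_for_perspective)
})

test_that("utilities outside the configured bounds are rejected", {
  spec <- three_state_spec(0.1, 0.05, mortality = 0.02)
  tr <- run_cohort_trace(spec, 5)
  vals <- spec$values
  vals$utility[vals$state == "baseline"] <- 1.3
  expect_error(accumulate_arm(tr, vals,
                              outcome_settings(horizon_cycles = 5)),
               "bounds")
  # the wider configured range admits worse-than-dead utilities
  vals$utility[vals$state == "baseline"] <- -0.2
  s_wide <- outcome_settings(horizon_cycles = 5,
                             utility_bounds = c(-1, 1))
  expect_s3_class(accumulate_arm(tr, vals, s_wide), "arm_outcome")
})

make_arm <- function(qalys, cost) {
  structure(list(qalys = qalys, cost_total_for_perspective = cost,
                 cost_healthcare = cost, cost_societal = 0,
                 life_years = qalys, perspective = "healthcare"),
            class = "arm_outcome")
}

test_that("ICER and INMB follow their defining formulas", {
  s <- outcome_settings(lambda = 30000)
  inc <- incremental(make_arm(5.25, 12000), make_arm(5.0, 10000), s)
  expect_equal(inc$delta_e, 0.25)
  expect_equal(inc$delta_c, 2000)
  expect_equal(inc$icer, 8000)
  expect_equal(inc$inmb, 0.25 * 30000 - 2000)  # 5500
  expect_equal(inc$dominance, "trade_off_ne_quadrant")
})

test_that("dominance quadrants suppress the ICER", {
  s <- outcome_settings(lambda = 30000)
  dom <- incremental(make_arm(5.1, 9500), make_arm(5.0, 10000), s)
  expect_equal(dom$dominance, "intervention_dominant")
  expect_true(is.na(dom$icer))
  dominated <- incremental(make_arm(4.9, 10500), make_arm(5.0, 10000), s)
  expect_equal(dominated$dominance, "comparator_dominant")
  expect_true(is.na(dominated$icer))
  sw <- incremental(make_arm(4.9, 9000), make_arm(5.0, 10000), s)
  expect_equal(sw$dominance, "trade_off_sw_quadrant")
  expect_equal(sw$icer, -1000 / -0.1)
  # zero effect: classified by cost sign, no ratio
  ze <- incremental(make_arm(5.0, 11000), make_arm(5.0, 10000), s)
  expect_equal(ze$dominance, "comparator_dominant")
  expect_true(is.na(ze$icer))
  eq <- incremental(make_arm(5.0, 10000), make_arm(5.0, 10000), s)
  expect_equal(eq$dominance, "equivalent")
  expect_equal(eq$inmb, 0)
})

test_that("identical arms give exactly zero increments", {
  spec <- three_state_spec(0.1, 0.05, mortality = 0.02,
                           excess_mortality = 0.01)
  tr <- run_cohort_trace(spec, 10)
  s <- outcome_settings(horizon_cycles = 10)
  a <- accumulate_arm(tr, spec$values, s)
  inc <- incremental(a, a, s)
  expect_identical(inc$delta_e, 0)
  expect_identical(inc$delta_c, 0)
  expect_identical(inc$inmb, 0)
})

test_that("the delivery cost is discounted and added to delta C", {
  s <- outcome_settings(lambda = 30000, discount_rate_costs = 0.03,
                        horizon_cycles = 3)
  inc <- incremental(make_arm(5.0, 10000), make_arm(5.0, 10000), s,
                     delivery_cost = intervention_cost(one_off = 100,
                                                       per_cycle = 10))
  expect_equal(inc$delta_c, 100 + 10 * sum(1.03^-(1:3)), tolerance = 1e-12)
})

test_that("raising intervention utility or cost moves dE / dC monotonically", {
  ps <- make_test_ps()
  base <- run_comparison(ps)
  up_u <- merge_overrides(ps, list(arms = list(intervention = list(
    state_values = list(deteriorated = list(utility = 0.7))))))
  up_c <- merge_overrides(ps, list(arms = list(intervention = list(
    state_values = list(deteriorated = list(cost_healthcare = 5000))))))
  expect_gt(run_comparison(up_u)$incremental$delta_e,
            base$incremental$delta_e)
  expect_gt(run_comparison(up_c)$incremental$delta_c,
            base$incremental$delta_c)
})

test_that("linear and piecewise EQ-5D mapping applies declared coefficients", {
  ident <- mapping_algorithm(0, 1, 0)
  expect_equal(map_to_eq5d(0.7, ident)$utility, 0.7)
  expect_equal(map_to_eq5d(0.7, ident)$se, 0)

  alg <- mapping_algorithm(0.2, 0.006, se = 0.08, score_range = c(0, 100))
  res <- map_to_eq5d(50, alg)
  expect_equal(res$utility, 0.5)
  expect_equal(res$se, 0.08)
  expect_error(map_to_eq5d(120, alg), "outside")
  expect_silent(map_to_eq5d(120, alg, extrapolate = TRUE))

  pw <- mapping_algorithm(se = 0.05, segments = tibble::tibble(
    lower = c(0, 50), upper = c(50, 100),
    intercept = c(0.1, 0.3), slope = c(0.004, 0.006)))
  expect_equal(map_to_eq5d(25, pw)$utility, 0.1 + 0.004 * 25)
  expect_equal(map_to_eq5d(75, pw)$utility, 0.3 + 0.006 * 75)
})

test_that("out-of-bounds mapped utilities are clamped with a warning", {
  alg <- mapping_algorithm(0.9, 0.01, se = 0.02, score_range = c(0, 100))
  expect_warning(res <- map_to_eq5d(50, alg), "clamped")
  expect_equal(res$utility, 1)
  expect_true(res$clamped)
})
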
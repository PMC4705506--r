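test_that("parameter sets round-trip through JSON", {
  fx <- synthetic_fixture(3)
  ps <- fx$parameter_set
  path <- withr::local_tempfile(fileext = ".json")
  write_parameter_set(ps, path)
  ps2 <- read_parameter_set(path)
  expect_equal(unclass(ps2), unclass(ps), tolerance = 1e-12)
  # canonical form is byte-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_parameter_set(ps2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("domain violations are reported at their path", {
  ps <- unclass(make_test_ps())
  ps$arms$control$state_values$baseline$utility <- 1.3
  report <- validate_parameter_set(ps)
  expect_true(any(report$severity == "error" &
    report$path == "arms.control.state_values.baseline.utility"))
  expect_error(as_parameter_set(ps), "validation")
})

test_that("dangling state references and unknown keys are rejected", {
  ps <- unclass(make_test_ps())
  ps$arms$control$transitions$incidence$to <- "frail"
  report <- validate_parameter_set(ps)
  expect_true(any(grepl("frail", report$message)))

  ps2 <- unclass(make_test_ps())
  ps2$favourite_colour <- "green"
  report2 <- validate_parameter_set(ps2)
  expect_true(any(report2$path == "favourite_colour" &
                  grepl("unknown key", report2$message)))

  ps3 <- unclass(make_test_ps())
  ps3$arms$control$transitions$incidence$speed <- 9
  report3 <- validate_parameter_set(ps3)
  expect_true(any(grepl("speed", report3$path)))
})

test_that("distribution targets and feasibility are validated", {
  ps <- unclass(make_test_ps())
  ps$distributions <- list(
    list(target = "arms.control.transitions.nonexistent.value",
         family = "beta", mean = 0.1, se = 0.01),
    list(target = "arms.control.transitions.incidence.value",
         family = "beta", mean = 0.5, se = 0.9)
  )
  report <- validate_parameter_set(ps)
  expect_true(any(grepl("does not resolve", report$message)))
  expect_true(any(grepl("infeasible", report$message)))
})

test_that("an empty override merge is the identity", {
  ps <- make_test_ps()
  merged <- merge_overrides(ps, list())
  expect_equal(unclass(merged), unclass(ps))
  expect_equal(merged$metadata$provenance, "default")
})

test_that("overriding one leaf changes it alone and flips its provenance", {
  ps <- make_test_ps()
  merged <- merge_overrides(ps, list(arms = list(control = list(
    state_values = list(baseline = list(utility = 0.9))))))
  expect_equal(merged$arms$control$state_values$baseline$utility, 0.9)
  expect_equal(merged$provenance,
               "arms.control.state_values.baseline.utility")
  expect_equal(merged$metadata$provenance, "user_provided")
  # nothing else changed
  stripped <- function(x) {
    x$provenance <- NULL
    x$metadata$provenance <- NULL
    x$arms$control$state_values$baseline$utility <- NULL
    unclass(x)
  }
  expect_equal(stripped(merged), stripped(ps))
})

test_that("overrides must resolve and the merged set must stay valid", {
  ps <- make_test_ps()
  expect_error(merge_overrides(ps, list(arms = list(control = list(
    transitions = list(falls = list(value = 0.2)))))), "does not resolve")
  # pushing competing exits above 1 fails engine validation
  expect_error(merge_overrides(ps, list(arms = list(control = list(
    transitions = list(incidence = list(value = 0.999)))))),
    "validation")
})

test_that("fixtures are deterministic per seed and distinct across seeds", {
  a <- synthetic_fixture(5, "falls_prevention")
  b <- synthetic_fixture(5, "falls_prevention")
  expect_identical(unclass(a$parameter_set), unclass(b$parameter_set))
  expect_identical(as.data.frame(a$life_table), as.data.frame(b$life_table))
  c <- synthetic_fixture(6, "falls_prevention")
  expect_false(identical(unclass(a$parameter_set),
                         unclass(c$parameter_set)))
})

test_that("fixture life tables are Gompertz-monotone and closed", {
  for (profile in c("generic_elderly", "falls_prevention",
                    "chronic_disease")) {
    fx <- synthetic_fixture(11, profile)
    q <- fx$life_table$mortality_prob
    expect_true(all(diff(q) > 0))
    expect_true(all(q >= 0 & q <= 1))
    expect_equal(q[length(q)], 1)
  }
})

test_that("fixtures validate cleanly and the arms genuinely differ", {
  fx <- synthetic_fixture(21, "chronic_disease")
  report <- validate_parameter_set(fx$parameter_set, fx$life_table)
  expect_equal(sum(report$severity == "error"), 0)
  ctl <- fx$parameter_set$arms$control
  int <- fx$parameter_set$arms$intervention
  expect_false(identical(ctl$transitions, int$transitions))
  expect_false(identical(ctl$state_values, int$state_values))
})

test_that("every fixture runs end-to-end through trace, outcomes and PSA", {
  for (profile in c("generic_elderly", "falls_prevention",
                    "chronic_disease")) {
    fx <- synthetic_fixture(31, profile)
    res <- run_comparison(fx$parameter_set, life_table = fx$life_table)
    expect_true(is.finite(res$incremental$inmb))
    psa <- run_psa(fx$parameter_set, n_draws = 100, seed = 1,
                   life_table = fx$life_table)
    expect_equal(nrow(psa$draws), 100)
    expect_true(all(is.finite(psa$draws$inmb)))
  }
})

test_that("life tables round-trip through CSV", {
  lt <- synthetic_fixture(2)$life_table
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path, population = attr(lt, "population"))
  expect_equal(lt2$age, lt$age)
  expect_equal(lt2$mortality_prob, lt$mortality_prob)
})
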
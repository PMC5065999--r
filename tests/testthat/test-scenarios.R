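test_that("the induction row resolves to the printed response probability", {
  spec <- build_arm("ada", analysis_request(10, 0.79))
  p <- resolve_row(spec$transitions$ada_induction, 0, series = spec$series)
  expect_equal(unname(p["ada_response"]), 0.868)
  expect_equal(unname(p["ada_complication"]), 0.0304)
  expect_equal(unname(p["unwell_steroids"]), 1 - 0.868 - 0.0304)
})

test_that("arms start where the treatment strategies say", {
  no <- build_arm("no_ada", analysis_request(5, 0.79))
  ada <- build_arm("ada", analysis_request(5, 0.79))
  expect_equal(no$initial_distribution, c(unwell_steroids = 1))
  expect_equal(ada$initial_distribution, c(ada_induction = 1))
  expect_equal(no$horizon_cycles, 20L)
})

test_that("the utility variant is scoped to the primary response state", {
  a79 <- build_arm("ada", analysis_request(10, 0.79))
  a82 <- build_arm("ada", analysis_request(10, 0.82))
  expect_equal(a79$states$ada_response$annual_utility, 0.79)
  expect_equal(a82$states$ada_response$annual_utility, 0.82)
  for (id in setdiff(names(a79$states), "ada_response"))
    expect_equal(a82$states[[id]]$annual_utility,
                 a79$states[[id]]$annual_utility)
  expect_equal(a82$states$cp_ada_response$annual_utility, 0.58)
})

test_that("an escalation fraction of zero reproduces the base arm", {
  base <- run_analysis(analysis_request(10, 0.79, "base"))
  none <- run_analysis(analysis_request(10, 0.79, "escalation"),
                       esc = escalation_policy(fraction_escalated = 0))
  expect_equal(none$icer, base$icer, tolerance = 1e-12)
  expect_equal(none$delta_cost, base$delta_cost, tolerance = 1e-9)
})

test_that("a de-escalation attempt rate of zero reproduces the escalation scenario", {
  esc <- run_analysis(analysis_request(10, 0.79, "escalation"))
  de0 <- run_analysis(analysis_request(10, 0.79, "deescalation"),
                      deesc = deescalation_policy(fraction_attempted = 0))
  expect_equal(de0$icer, esc$icer, tolerance = 1e-12)
})

test_that("the effective de-escalated fraction is the product of the printed rates", {
  expect_equal(deescalation_policy()$effective_fraction, 0.54 * 0.63)
})

test_that("escalated dosing is costed at double the every-other-week drug cost", {
  pol <- escalation_policy()
  expect_equal(pol$escalated_cost, 2 * 6 * 740.36)
})

test_that("ICERs are ordered base <= de-escalation <= escalation and increase with horizon", {
  for (u in c(0.79, 0.82)) {
    icers <- sapply(c("base", "deescalation", "escalation"), function(sc)
      sapply(c(5, 10, 15), function(h)
        run_analysis(analysis_request(h, u, sc))$icer))
    # scenario ordering at each horizon
    for (i in 1:3) {
      expect_lte(icers[i, "base"], icers[i, "deescalation"])
      expect_lte(icers[i, "deescalation"], icers[i, "escalation"])
    }
    # horizon ordering within each scenario
    for (sc in colnames(icers)) expect_true(all(diff(icers[, sc]) > 0))
  }
})

test_that("the higher response-utility variant never increases the ICER", {
  for (sc in c("base", "escalation")) for (h in c(5, 10, 15)) {
    i79 <- run_analysis(analysis_request(h, 0.79, sc))$icer
    i82 <- run_analysis(analysis_request(h, 0.82, sc))$icer
    expect_lte(i82, i79)
  }
})

test_that("the model-implied mean time to escalation matches the observed timing", {
  spec <- build_arm("ada", analysis_request(10, 0.79, "escalation"))
  cc <- collapse_trace(run_cohort(spec))
  inflow <- cc[, "ada_escalated"]        # entry state holds one cycle's inflow
  k <- seq_len(nrow(cc)) - 1
  mean_weeks <- 13 * sum(k * inflow) / sum(inflow)
  # observed: escalation required after a mean 59.3 (+/-70.5) weeks
  expect_gt(mean_weeks, 45)
  expect_lt(mean_weeks, 75)
})

test_that("analysis requests validate their inputs", {
  expect_error(analysis_request(7), "horizon")
  expect_error(analysis_request(10, 0.5), "response_utility")
  expect_error(build_arm("infliximab"), "arg")
})
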
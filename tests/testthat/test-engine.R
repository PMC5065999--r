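test_that("geometric toy follows the closed-form decay", {
  tr <- run_cohort(toy_geometric(p_stay = 0.9, horizon = 20L))
  for (k in c(0, 1, 5, 10, 20))
    expect_equal(unname(tr$occupancy[k + 1, "alive"]), 0.9^k)
})

test_that("trace rows conserve mass and the initial row matches the start distribution", {
  specs <- list(
    build_arm("no_ada", analysis_request(10, 0.79)),
    build_arm("ada", analysis_request(10, 0.79)),
    build_arm("ada", analysis_request(15, 0.79, "escalation")),
    build_arm("ada", analysis_request(15, 0.79, "deescalation")))
  for (s in seq_len(8))
    specs[[length(specs) + 1]] <- generate_model(generator_config(
      n_states = 3 + s, fraction_time_varying = 0.4, seed = 100 + s))
  for (spec in specs) {
    tr <- run_cohort(spec)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    expect_true(all(tr$occupancy >= -1e-14 & tr$occupancy <= 1 + 1e-14))
    cc <- collapse_trace(tr)
    init <- spec$initial_distribution
    expect_equal(unname(cc[1, names(init)]), unname(init))
  }
})

test_that("death occupancy is non-decreasing", {
  for (spec in list(build_arm("ada", analysis_request(10, 0.79)),
                    generate_model(generator_config(seed = 5)))) {
    tr <- run_cohort(spec)
    cc <- collapse_trace(tr)
    expect_true(all(diff(cc[, "death"]) >= -1e-14))
  }
})

test_that("tunnel expansion creates 21 copies and leaves clock-free models untouched", {
  spec <- load_model_spec(uc_fixture_path("ada"))
  ex <- expand_tunnels(spec)
  copies <- grep("^cp_ada_response", names(ex$states), value = TRUE)
  expect_length(copies, 21)
  expect_false("cp_ada_response" %in% names(ex$states))
  # every copy inherits the original economics
  for (cp in copies) {
    expect_equal(ex$states[[cp]]$cost_per_cycle, 4442)
    expect_equal(ex$states[[cp]]$annual_utility, 0.58)
  }
  toy <- toy_geometric()
  ex_toy <- expand_tunnels(toy)
  expect_equal(names(ex_toy$states), names(toy$states))
})

test_that("expanded-copy occupancy collapses back to a conserved total", {
  spec <- build_arm("no_ada", analysis_request(10, 0.79))
  tr <- run_cohort(spec)
  cc <- collapse_trace(tr)
  manual <- rowSums(tr$occupancy[, grep("^cp_ada_response",
                                        colnames(tr$occupancy))])
  expect_equal(unname(cc[, "cp_ada_response"]), unname(manual))
})

test_that("with a constant retention series, tunnel expansion is equivalent to a fixed-probability row", {
  mk <- function(residence) {
    series <- list(const = constant_series(70))
    stay <- if (residence)
      transition_entry("resp", "series", series = "const",
                       index = "residence", mode = "direct")
    else transition_entry("resp", "fixed", value = 70)
    markov_spec(
      states = list(
        health_state("resp", cost_per_cycle = 500, annual_utility = 0.7),
        health_state("out", cost_per_cycle = 100, annual_utility = 0.3),
        health_state("dead", is_death = TRUE)),
      transitions = list(
        transition_row("resp", list(
          stay,
          transition_entry("dead", "fixed", value = 2),
          transition_entry("out", "complement")),
          residence_clock = residence),
        transition_row("out", list(
          transition_entry("resp", "fixed", value = 10),
          transition_entry("dead", "fixed", value = 5),
          transition_entry("out", "complement")))),
      series = series,
      initial_distribution = c(resp = 1), horizon_cycles = 30L,
      name = "const_test")
  }
  tr_res <- run_cohort(mk(TRUE))
  tr_fix <- run_cohort(mk(FALSE))
  cc <- collapse_trace(tr_res)
  expect_equal(cc[, c("resp", "out", "dead")],
               tr_fix$occupancy[, c("resp", "out", "dead")],
               tolerance = 1e-12)
  e_res <- accumulate(tr_res)
  e_fix <- accumulate(tr_fix)
  expect_equal(e_res$total_cost, e_fix$total_cost)
  expect_equal(e_res$total_qalys, e_fix$total_qalys)
})
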
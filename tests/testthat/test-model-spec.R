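expected_states <- c(
  "ongoing_steroids", "steroid_response", "unwell_steroids",
  "steroid_complication", "surgery", "surgery_response",
  "chronic_pouchitis", "surgical_complication", "ada_induction",
  "ada_response", "ada_complication", "cp_ada_response", "cp_unwell",
  "cp_ada_complication", "cp_surgery", "cp_steroid_complication",
  "cp_surgery_response", "cp_surgical_complication", "death")

test_that("both shipped arms load, validate, and declare the full state set", {
  for (arm in c("no_ada", "ada")) {
    spec <- load_model_spec(uc_fixture_path(arm))
    expect_s3_class(spec, "markov_spec")
    expect_setequal(names(spec$states), expected_states)
    expect_true(spec$states$death$is_death)
    expect_equal(sum(spec$initial_distribution), 1)
  }
})

test_that("the arms differ only where the disease model says they should", {
  no <- load_model_spec(uc_fixture_path("no_ada"))
  ada <- load_model_spec(uc_fixture_path("ada"))
  # shared state economics
  for (id in expected_states) {
    expect_equal(ada$states[[id]]$cost_per_cycle, no$states[[id]]$cost_per_cycle)
    expect_equal(ada$states[[id]]$annual_utility, no$states[[id]]$annual_utility)
  }
  # arm-specific pieces: start state, pouchitis curve, pouchitis
  # complication row, pouchitis entry probability
  expect_equal(names(no$initial_distribution), "unwell_steroids")
  expect_equal(names(ada$initial_distribution), "ada_induction")
  expect_equal(no$series$cp_response$values, cp_naive_values)
  expect_equal(ada$series$cp_response$values, cp_exposed_values)
  pr_no <- resolve_row(no$transitions$cp_ada_complication)
  pr_ada <- resolve_row(ada$transitions$cp_ada_complication)
  expect_equal(unname(pr_no[c("cp_ada_response", "cp_unwell", "cp_surgery", "death")]),
               c(0.60, 0.19, 0.19, 0.02))
  expect_equal(unname(pr_ada[c("cp_ada_response", "cp_unwell", "cp_surgery", "death")]),
               c(0.51, 0.235, 0.235, 0.02))
})

test_that("complement resolution reproduces the printed fixed entries", {
  spec <- load_model_spec(uc_fixture_path("no_ada"))
  p <- resolve_row(spec$transitions$ongoing_steroids)
  expect_equal(unname(p[c("steroid_response", "unwell_steroids",
                          "steroid_complication", "surgery")]),
               c(0.3392, 0.5711, 0.0280, 1 - 0.3392 - 0.5711 - 0.0280))
  p <- resolve_row(spec$transitions$steroid_complication)
  expect_equal(unname(p["death"]), 0.02)
  p <- resolve_row(spec$transitions$surgery)
  expect_equal(unname(p["surgery_response"]), 1 - 0.128 - 0.025)
  p <- resolve_row(spec$transitions$surgical_complication)
  expect_equal(unname(p["death"]), 0.005)
})

test_that("a row whose fixed entries exhaust the mass leaves a zero complement", {
  row <- transition_row("a", list(
    transition_entry("b", "fixed", value = 60),
    transition_entry("c", "fixed", value = 40),
    transition_entry("d", "complement")))
  p <- resolve_row(row)
  expect_equal(unname(p["d"]), 0)
  expect_equal(sum(p), 1)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(transition_row("a", list(
    transition_entry("b", "fixed", value = 80),
    transition_entry("c", "fixed", value = 40),
    transition_entry("d", "complement"))), "sum to 120")
  expect_error(transition_row("a", list(
    transition_entry("b", "complement"),
    transition_entry("c", "complement"))), "exactly one complement")
  expect_error(transition_row("a", list(
    transition_entry("b", "fixed", value = 50))), "complement")
  expect_error(transition_entry("b", "fixed", value = 120), "outside")
  expect_error(transition_entry("b", "fixed", value = 50, lo = 60, hi = 70),
               "bracket")
  # referential integrity
  good <- toy_geometric()
  bad <- good
  bad$transitions$alive$entries[[1]]$to <- c(ghost = 1)
  expect_error(validate_markov_spec(bad), "ghost")
  expect_error(markov_spec(
    states = list(health_state("a"), health_state("a"),
                  health_state("dead", is_death = TRUE)),
    transitions = list(), initial_distribution = c(a = 1)),
    "duplicate state id")
  bad <- good
  bad$initial_distribution <- c(alive = 0.7)
  expect_error(validate_markov_spec(bad), "sums to 0.7")
})

test_that("serialization round-trips through the config format", {
  spec <- load_model_spec(uc_fixture_path("ada"))
  dump <- serialize_model_spec(spec)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(dump, tmp)
  back <- load_model_spec(tmp)
  expect_equal(names(back$states), names(spec$states))
  for (id in names(spec$states))
    expect_equal(back$states[[id]][c("cost_per_cycle", "annual_utility",
                                     "is_death")],
                 spec$states[[id]][c("cost_per_cycle", "annual_utility",
                                     "is_death")])
  for (from in names(spec$transitions))
    for (k in c(0L, 3L, 25L))
      expect_equal(
        resolve_row(back$transitions[[from]], k, series = back$series),
        resolve_row(spec$transitions[[from]], k, series = spec$series))
})

test_that("every resolved row sums to one at any clock position", {
  for (arm in c("no_ada", "ada")) {
    spec <- expand_tunnels(load_model_spec(uc_fixture_path(arm)))
    for (row in spec$transitions)
      for (k in c(0L, 1L, 7L, 20L, 21L, 60L))
        expect_equal(sum(resolve_row(row, k, series = spec$series)), 1,
                     tolerance = 1e-12)
  }
})
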
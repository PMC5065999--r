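test_that("beta and gamma moment matching round-trip their targets", {
  for (m in c(0.44, 0.58, 0.79, 0.82)) for (hw in c(0.11, 0.21)) {
    par <- beta_from_moments(m, hw / 1.96)
    mean_back <- par$shape1 / (par$shape1 + par$shape2)
    var_back <- par$shape1 * par$shape2 /
      ((par$shape1 + par$shape2)^2 * (par$shape1 + par$shape2 + 1))
    expect_equal(mean_back, m, tolerance = 1e-9)
    expect_equal(sqrt(var_back), hw / 1.96, tolerance = 1e-9)
  }
  for (u in c(0.16, 0.32, 0.37)) {
    par <- gamma_decrement_from_moments(u, 0.08)
    expect_equal(par$shape * par$scale, 1 - u, tolerance = 1e-9)
    expect_equal(sqrt(par$shape) * par$scale, 0.08, tolerance = 1e-9)
  }
  expect_error(beta_from_moments(0.5, 0.6), "beta")
  expect_error(psa_distribution("cost", 100, -1), "non-negative")
})

test_that("parameter samplers recover their target means", {
  set.seed(7)
  n <- 10000
  # normal costs and beta utilities: unbiased, 3-SE recovery
  for (p in list(c(917, 0.25), c(37159, 0.25))) {
    d <- psa_distribution("cost", p[1], p[2])
    x <- d$sample(n)
    expect_lt(abs(mean(x) - p[1]), 3 * stats::sd(x) / sqrt(n))
  }
  for (p in list(c(0.79, 0.21), c(0.58, 0.15), c(0.44, 0.11))) {
    d <- psa_distribution("utility", p[1], p[2])
    expect_equal(d$family, "beta")
    x <- d$sample(n)
    expect_lt(abs(mean(x) - p[1]), 3 * stats::sd(x) / sqrt(n))
  }
  # gamma-on-decrement utilities are clipped to [0, 1]; allow the small
  # clipping bias on top of the Monte-Carlo band
  for (p in list(c(0.16, 0.16), c(0.32, 0.31), c(0.37, 0.24))) {
    d <- psa_distribution("utility", p[1], p[2])
    expect_equal(d$family, "gamma_on_decrement")
    x <- d$sample(n)
    expect_lt(abs(mean(x) - p[1]), 3 * stats::sd(x) / sqrt(n) + 0.01)
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("PSA is deterministic given the seed", {
  a <- sample_psa(analysis_request(5, 0.79), n_draws = 200, seed = 42)
  b <- sample_psa(analysis_request(5, 0.79), n_draws = 200, seed = 42)
  c <- sample_psa(analysis_request(5, 0.79), n_draws = 200, seed = 43)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws$cost_ada, c$draws$cost_ada))
})

test_that("degenerate distributions reproduce the base-case ICER in every draw", {
  base <- run_analysis(analysis_request(10, 0.79))
  psa <- sample_psa(analysis_request(10, 0.79), n_draws = 50, seed = 1,
                    halfwidth_scale = 0)
  icers <- psa$draws$delta_cost / psa$draws$delta_qalys
  expect_equal(icers, rep(base$icer, 50), tolerance = 1e-9)
  expect_equal(psa$draws$cost_ada,
               rep(attr(base, "ada")$total_cost, 50), tolerance = 1e-9)
})

test_that("exposure re-pricing equals a literal model re-run for a sampled draw", {
  req <- analysis_request(10, 0.79)
  psa <- sample_psa(req, n_draws = 3, seed = 99)
  set.seed(99)
  pars <- sample_parameters(build_arm("ada", req), 3)
  for (i in 1:3) {
    ov <- list(costs = pars$cost[i, ], utilities = pars$utility[i, ])
    ov$costs <- ov$costs[names(ov$costs) != "death"]
    ov$utilities <- ov$utilities[names(ov$utilities) != "death"]
    spec <- build_arm("ada", req, overrides = ov)
    res <- accumulate(run_cohort(spec))
    expect_equal(psa$draws$cost_ada[i], res$total_cost, tolerance = 1e-9)
    expect_equal(psa$draws$qalys_ada[i], res$total_qalys, tolerance = 1e-9)
  }
})

test_that("the acceptability curve starts at the cost-saving fraction and is monotone for tight distributions", {
  psa <- sample_psa(analysis_request(10, 0.79), n_draws = 500, seed = 5)
  cc <- ceac(psa, c(0, 25000, 50000))
  expect_equal(cc$probability_cost_effective[1],
               mean(psa$draws$delta_cost < 0))
  tight <- sample_psa(analysis_request(10, 0.79), n_draws = 500, seed = 5,
                      halfwidth_scale = 0.05)
  curve <- ceac(tight, seq(0, 200000, by = 10000))
  expect_true(all(tight$draws$delta_qalys > 0))
  expect_true(all(diff(curve$probability_cost_effective) >= 0))
})

test_that("sharing draws across arms correlates the common parameters", {
  psa_ind <- sample_psa(analysis_request(5, 0.79), n_draws = 300, seed = 8)
  psa_sh <- sample_psa(analysis_request(5, 0.79), n_draws = 300, seed = 8,
                       share_draws = TRUE)
  # with shared draws, delta QALYs varies far less than with independent ones
  expect_lt(stats::sd(psa_sh$draws$delta_qalys),
            0.5 * stats::sd(psa_ind$draws$delta_qalys))
})

test_that("a zero-width parameter interval gives zero tornado spread and the base ICER", {
  base <- run_analysis(analysis_request(10, 0.79))
  par <- data.frame(parameter = "cost.ada_response", kind = "cost",
                    state = "ada_response", from = NA, to = NA,
                    base = 4442, low = 4442, high = 4442)
  e <- one_way(analysis_request(10, 0.79), par)
  expect_equal(e$spread, 0)
  expect_equal(e$icer_at_low, base$icer, tolerance = 1e-12)
})

test_that("one-way bounds use printed CIs where available and +/-25% otherwise", {
  tab <- param_table(analysis_request(10, 0.79))
  a <- tab[tab$parameter == "prob.ongoing_steroids.steroid_response", ]
  expect_equal(c(a$low, a$high), c(28.09, 40.33))
  b <- tab[tab$parameter == "prob.surgery_response.chronic_pouchitis", ]
  expect_equal(c(b$low, b$high), c(11.70 * 0.75, 11.70 * 1.25))
  co <- tab[tab$parameter == "cost.ongoing_steroids", ]
  expect_equal(c(co$low, co$high), c(917 * 0.75, 917 * 1.25))
  u <- tab[tab$parameter == "utility.unwell_steroids", ]
  expect_equal(c(u$low, u$high), c(0.01, 0.63))
})

test_that("the tornado ranks drug-cost and unwell-utility parameters high and surgical-complication probabilities low", {
  tor <- tornado(analysis_request(10, 0.79))
  top10 <- utils::head(tor$entries$parameter, 10)
  expect_true("cost.ada_response" %in% top10)
  expect_true("utility.unwell_steroids" %in% top10)
  n <- nrow(tor$entries)
  rank_surg <- match("prob.surgery.surgical_complication",
                     tor$entries$parameter)
  rank_hosp <- match("prob.surgical_complication.surgery_response",
                     tor$entries$parameter)
  expect_gt(rank_surg, n / 2)
  expect_gt(rank_hosp, n / 2)
})
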
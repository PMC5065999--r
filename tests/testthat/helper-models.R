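# Small models built in code for engine and economics oracles.

# two-state toy: stay with probability p_stay, otherwise die
toy_geometric <- function(p_stay = 0.9, cost = 100, utility = 0.8,
                          horizon = 20L, rate = 0) {
  markov_spec(
    states = list(
      health_state("alive", cost_per_cycle = cost, annual_utility = utility),
      health_state("dead", is_death = TRUE)),
    transitions = list(
      transition_row("alive", list(
        transition_entry("alive", "fixed", value = 100 * p_stay),
        transition_entry("dead", "complement")))),
    initial_distribution = c(alive = 1),
    annual_discount_rate = rate, horizon_cycles = horizon,
    name = "toy_geometric")
}

# one absorbing live state (death edge present with probability zero)
single_state_spec <- function(utility = 0.8, horizon = 4L, rate = 0) {
  markov_spec(
    states = list(
      health_state("well", cost_per_cycle = 0, annual_utility = utility),
      health_state("dead", is_death = TRUE)),
    transitions = list(
      transition_row("well", list(
        transition_entry("well", "fixed", value = 100),
        transition_entry("dead", "complement")))),
    initial_distribution = c(well = 1),
    annual_discount_rate = rate, horizon_cycles = horizon,
    name = "single_state")
}

# constant retention series (useful for tunnel-invariance checks)
constant_series <- function(value = 70, name = "const") {
  retention_series(name, rep(value, 21))
}

# the printed previously-exposed pouchitis curve (15% discount of the
# naive curve, one decimal)
cp_naive_values <- c(62.6, 61.2, 59.9, 58.6, 57.3, 56.1, 54.9, 53.7, 52.5,
                     51.4, 50.3, 49.2, 48.1, 47.0, 46.0, 45.0, 44.0, 43.1,
                     42.1, 41.2, 40.2)
cp_exposed_values <- c(53.2, 52.0, 50.9, 49.8, 48.7, 47.7, 46.7, 45.6, 44.6,
                       43.7, 42.8, 41.8, 40.9, 40.0, 39.1, 38.3, 37.4, 36.6,
                       35.8, 35.0, 34.2)

uc_maintenance_values <- c(86.8, 73.3, 66.5, 62.0, 58.7, 56.2, 54.1, 52.4,
                           50.9, 49.6, 48.5, 47.5, 46.5, 45.7, 45.0, 44.3,
                           43.6, 43.0, 42.4, 41.9, 41.4)
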
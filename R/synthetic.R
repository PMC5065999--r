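# Random structurally-valid cohort models and a per-patient
# microsimulation oracle. Both exist so the cohort engine and the
# economics can be validated independently of the shipped disease model:
# the generator produces arbitrary state graphs with complement-resolved,
# possibly time-varying rows, and the microsimulation estimates the same
# discounted quantities by averaging simulated individual trajectories.

#' Configuration for the random model generator
#'
#' @param n_states number of non-death states (>= 2).
#' @param fraction_time_varying fraction of states given residence-clock
#'   retention-series dynamics.
#' @param cost_range per-cycle cost interval (CA$) to draw from; defaults
#'   to the range spanned by the shipped disease model.
#' @param utility_range annual-utility interval to draw from.
#' @param horizon_cycles horizon of generated models.
#' @param seed integer seed making generation deterministic.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_states = 6L, fraction_time_varying = 0.3,
                             cost_range = c(0, 37159),
                             utility_range = c(0.16, 0.82),
                             horizon_cycles = 40L, seed = 1L) {
  stopifnot(n_states >= 2, fraction_time_varying >= 0,
            fraction_time_varying <= 1)
  structure(list(n_states = as.integer(n_states),
                 fraction_time_varying = fraction_time_varying,
                 cost_range = cost_range, utility_range = utility_range,
                 horizon_cycles = as.integer(horizon_cycles),
                 seed = as.integer(seed)),
            class = "generator_config")
}

random_series <- function(name) {
  start <- stats::runif(1, 50, 95)
  drops <- stats::runif(20, 0, 0.08)
  retention_series(name, round(start * cumprod(c(1, 1 - drops)), 1))
}

#' Generate a random, structurally valid cohort model
#'
#' Builds a random directed state graph over `n_states` transient states
#' plus one absorbing death state. Each row draws 1-3 fixed targets from
#' a Dirichlet-style simplex and designates one complement entry;
#' time-varying states get a residence-clock row driven by a random
#' non-increasing retention series. Every state has a positive death
#' probability, so death is always reachable. Generation is deterministic
#' given `config$seed` and the result always passes
#' [validate_markov_spec()] by construction.
#'
#' @param config a [generator_config()].
#' @return a [markov_spec()].
#' @export
generate_model <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_states
  ids <- sprintf("s%02d", seq_len(n))
  states <- lapply(seq_len(n), function(i)
    health_state(ids[i], paste("synthetic state", i),
                 cost_per_cycle = stats::runif(1, config$cost_range[1L],
                                               config$cost_range[2L]),
                 annual_utility = stats::runif(1, config$utility_range[1L],
                                               config$utility_range[2L]),
                 cost_rel_halfwidth = 0.25,
                 utility_halfwidth = stats::runif(1, 0.05, 0.2)))
  states <- c(states, list(health_state("death", "Death", is_death = TRUE)))

  n_tv <- round(config$fraction_time_varying * n)
  tv <- if (n_tv > 0) sample(ids, n_tv) else character(0)
  series <- lapply(seq_along(tv), function(i) random_series(paste0("ret", i)))
  if (length(tv)) names(series) <- paste0("ret", seq_along(tv))

  transitions <- lapply(seq_len(n), function(i) {
    id <- ids[i]
    others <- setdiff(ids, id)
    k <- sample(min(3, length(others)), 1L)
    targets <- c(sample(others, k), "death")
    # random point on the simplex over targets + complement
    w <- -log(stats::runif(length(targets) + 1L))
    w <- w / sum(w)
    if (id %in% tv) {
      entries <- c(
        list(transition_entry(id, "series",
                              series = names(series)[match(id, tv)],
                              index = "residence",
                              mode = sample(c("direct", "conditional"), 1L))),
        lapply(seq_along(targets), function(j)
          transition_entry(targets[j], "fixed",
                           value = 100 * w[j] * 0.5)),
        list(transition_entry(others[1L], "complement")))
      transition_row(id, entries, residence_clock = TRUE)
    } else {
      entries <- c(
        lapply(seq_along(targets), function(j)
          transition_entry(targets[j], "fixed", value = 100 * w[j])),
        list(transition_entry(sample(c(id, others), 1L), "complement")))
      transition_row(id, entries)
    }
  })

  init <- -log(stats::runif(n))
  init <- init / sum(init)
  markov_spec(states, transitions, series,
              stats::setNames(init, ids),
              horizon_cycles = config$horizon_cycles,
              name = sprintf("synthetic_n%d_seed%d", n, config$seed))
}

#' Per-patient microsimulation oracle
#'
#' Simulates individual trajectories through the tunnel-expanded model,
#' sampling each transition from the same per-cycle resolved
#' probabilities the cohort engine uses, and accruing discounted costs
#' (including the one-time predecessor-cost charge on death) and QALYs
#' per patient. The patient-mean estimates converge to the cohort-engine
#' totals, which gives an independent stochastic check of the matrix
#' propagation and the economic accounting.
#'
#' @param spec a [markov_spec()].
#' @param n_patients number of simulated patients.
#' @param seed integer seed.
#' @return a `microsim_result`: means and standard errors of discounted
#'   cost and QALYs, and the empirical state-frequency trace (collapsed
#'   over tunnel copies).
#' @export
microsimulate <- function(spec, n_patients = 10000L, seed = 1L) {
  stopifnot(n_patients >= 1)
  spec <- expand_tunnels(spec)
  ids <- state_ids(spec)
  H <- spec$horizon_cycles
  len <- spec$cycle_length_years
  cost_s <- vapply(spec$states, `[[`, 0, "cost_per_cycle")
  util_s <- vapply(spec$states, `[[`, 0, "annual_utility")
  is_death <- vapply(spec$states, `[[`, FALSE, "is_death")

  rs <- resolve_static(spec)
  set.seed(seed)
  init_idx <- match(names(spec$initial_distribution), ids)
  state <- init_idx[sample.int(length(init_idx), n_patients, replace = TRUE,
                               prob = spec$initial_distribution)]
  cost_p <- numeric(n_patients)
  qaly_p <- numeric(n_patients)
  freq <- matrix(0, H + 1L, length(ids), dimnames = list(NULL, ids))
  freq[1L, ] <- tabulate(state, length(ids)) / n_patients

  for (k in 0:(H - 1L)) {
    d <- discount_factor(k, spec$annual_discount_rate, len)
    cost_p <- cost_p + cost_s[state] * d
    qaly_p <- qaly_p + util_s[state] * len * d
    P <- if (length(rs$dynamic)) update_dynamic(rs$P, spec, rs$dynamic, k)
         else rs$P
    nxt <- state
    for (s in unique(state)) {
      i <- which(state == s)
      nxt[i] <- sample.int(length(ids), length(i), replace = TRUE,
                           prob = P[s, ])
    }
    died <- !is_death[state] & is_death[nxt]
    cost_p[died] <- cost_p[died] + cost_s[state[died]] * d
    state <- nxt
    freq[k + 2L, ] <- tabulate(state, length(ids)) / n_patients
  }

  grp <- attr(spec, "collapse")[ids]
  structure(list(
    mean_cost = mean(cost_p), se_cost = stats::sd(cost_p) / sqrt(n_patients),
    mean_qalys = mean(qaly_p), se_qalys = stats::sd(qaly_p) / sqrt(n_patients),
    trace = t(rowsum(t(freq), grp)),
    n_patients = n_patients, seed = seed, model = spec$name),
    class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result>", x$model, "-", x$n_patients, "patients\n")
  cat(sprintf("  cost : $%s (SE %s)\n",
              format(round(x$mean_cost), big.mark = ","),
              format(round(x$se_cost), big.mark = ",")))
  cat(sprintf("  QALYs: %.3f (SE %.4f)\n", x$mean_qalys, x$se_qalys))
  invisible(x)
}
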
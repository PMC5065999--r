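# One-way deterministic sensitivity analysis (tornado data), probabilistic
# sensitivity analysis and cost-effectiveness acceptability curves.
#
# PSA note: transition probabilities are held fixed (only costs and utility
# scores are sampled), so the cohort trace is identical across draws and
# total cost / QALYs are linear in the per-state discounted exposures
# returned by accumulate(). Draws therefore re-price two exposure vectors
# instead of re-running the cohort, which is exact and ~10^4 times faster;
# tests verify equality against literal re-runs.

# ---- distributions ----------------------------------------------------------

#' Beta parameters by moment matching
#'
#' @param mean,sd target mean and standard deviation; requires
#'   `sd^2 < mean * (1 - mean)`.
#' @return list with `shape1`, `shape2`.
#' @export
beta_from_moments <- function(mean, sd) {
  if (sd <= 0) stop("sd must be positive")
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop("sd too large for a beta distribution with mean ", mean)
  a <- mean * (mean * (1 - mean) / v - 1)
  list(shape1 = a, shape2 = (1 - mean) * a / mean)
}

#' Gamma parameters for a utility decrement by moment matching
#'
#' For utility scores close to 0 the decrement `1 - u` is modelled as a
#' gamma variable with the target mean and standard deviation.
#'
#' @param utility base utility score.
#' @param sd standard deviation of the utility (and the decrement).
#' @return list with `shape`, `scale` for the decrement `1 - u`.
#' @export
gamma_decrement_from_moments <- function(utility, sd) {
  if (sd <= 0) stop("sd must be positive")
  d <- 1 - utility
  if (d <= 0) stop("utility must be below 1")
  list(shape = (d / sd)^2, scale = sd^2 / d)
}

#' Distribution assignment for an uncertain parameter
#'
#' Costs are normal (truncated at 0 when sampling); utility scores far
#' from 0 (>= `beta_threshold`) are beta; utility scores close to 0 are
#' transformed to the decrement `1 - u` and modelled gamma. Printed
#' half-widths are read as 95% intervals, so `sd = halfwidth / 1.96`.
#'
#' @param kind `"cost"` or `"utility"`.
#' @param mean base value.
#' @param halfwidth 95% half-width: relative for costs (0.25 = +/-25%),
#'   absolute for utilities.
#' @param beta_threshold utilities at or above this use beta; below it,
#'   gamma on the decrement.
#' @return a `distribution_spec` list with a `sample(n)` function.
#' @export
psa_distribution <- function(kind = c("cost", "utility"), mean, halfwidth,
                             beta_threshold = 0.4) {
  kind <- match.arg(kind)
  if (halfwidth < 0) stop("halfwidth must be non-negative (SD <= 0 invalid)")
  if (halfwidth == 0 || mean == 0) {
    family <- "degenerate"
    sample <- function(n) rep(mean, n)
  } else if (kind == "cost") {
    family <- "normal"
    sd <- halfwidth * mean / 1.96
    sample <- function(n) pmax(stats::rnorm(n, mean, sd), 0)
  } else if (mean >= beta_threshold) {
    family <- "beta"
    par <- beta_from_moments(mean, halfwidth / 1.96)
    sample <- function(n) stats::rbeta(n, par$shape1, par$shape2)
  } else {
    family <- "gamma_on_decrement"
    par <- gamma_decrement_from_moments(mean, halfwidth / 1.96)
    sample <- function(n)
      pmin(pmax(1 - stats::rgamma(n, shape = par$shape, scale = par$scale), 0), 1)
  }
  structure(list(kind = kind, family = family, mean = mean,
                 halfwidth = halfwidth, sample = sample),
            class = "distribution_spec")
}

#' Sample cost and utility parameters of a model
#'
#' @param spec a [markov_spec()].
#' @param n_draws number of draws.
#' @param halfwidth_scale multiplier on all half-widths (0 gives
#'   degenerate draws at the base values).
#' @return list of matrices `cost` and `utility` (`n_draws` rows, one
#'   column per state).
#' @export
sample_parameters <- function(spec, n_draws, halfwidth_scale = 1) {
  ids <- state_ids(spec)
  cost <- matrix(0, n_draws, length(ids), dimnames = list(NULL, ids))
  util <- cost
  for (s in spec$states) {
    if (s$is_death) next
    cost[, s$id] <- psa_distribution("cost", s$cost_per_cycle,
                                     s$cost_rel_halfwidth * halfwidth_scale)$sample(n_draws)
    util[, s$id] <- psa_distribution("utility", s$annual_utility,
                                     s$utility_halfwidth * halfwidth_scale)$sample(n_draws)
  }
  list(cost = cost, utility = util)
}

# ---- probabilistic sensitivity analysis -------------------------------------

price_exposure <- function(econ, pars) {
  ex <- econ$exposure
  cost <- as.vector(pars$cost[, ex$state, drop = FALSE] %*%
                      (ex$occupancy + ex$death_flow))
  qaly <- as.vector(pars$utility[, ex$state, drop = FALSE] %*% ex$occupancy) *
    econ$cycle_length_years
  list(cost = cost, qaly = qaly)
}

#' Probabilistic sensitivity analysis
#'
#' Samples every state cost and utility from its assigned distribution
#' and re-prices both arms per draw (transition probabilities stay at
#' base, as in the deterministic analysis). Draws are sampled
#' independently for the two arms by default; `share_draws = TRUE`
#' correlates the arms through common parameter draws instead.
#'
#' @param request an [analysis_request()].
#' @param n_draws number of PSA draws.
#' @param seed integer seed; results are reproducible given the seed.
#' @param share_draws share parameter draws between arms.
#' @param halfwidth_scale multiplier on all half-widths (testing hook).
#' @return a `psa_result` with a data frame `draws` (per-draw cost and
#'   QALYs per arm and their increments).
#' @export
sample_psa <- function(request = analysis_request(), n_draws = 10000L,
                       seed = 1L, share_draws = FALSE, halfwidth_scale = 1) {
  stopifnot(n_draws >= 1)
  ada_spec <- build_arm("ada", request)
  no_spec <- build_arm("no_ada", request)
  ada <- accumulate(run_cohort(ada_spec))
  no <- accumulate(run_cohort(no_spec))

  set.seed(seed)
  pa <- sample_parameters(ada_spec, n_draws, halfwidth_scale)
  pn <- if (share_draws) {
    shared <- intersect(colnames(pa$cost), state_ids(no_spec))
    pn <- sample_parameters(no_spec, n_draws, halfwidth_scale)
    pn$cost[, shared] <- pa$cost[, shared]
    pn$utility[, shared] <- pa$utility[, shared]
    pn
  } else sample_parameters(no_spec, n_draws, halfwidth_scale)

  a <- price_exposure(ada, pa)
  n <- price_exposure(no, pn)
  draws <- data.frame(
    draw = seq_len(n_draws),
    cost_ada = a$cost, qalys_ada = a$qaly,
    cost_no_ada = n$cost, qalys_no_ada = n$qaly,
    delta_cost = a$cost - n$cost, delta_qalys = a$qaly - n$qaly)
  structure(list(draws = draws, n_draws = n_draws, seed = seed,
                 share_draws = share_draws, request = request),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws, seed", x$seed, "\n")
  cat(sprintf("  mean delta cost $%s, mean delta QALYs %.3f, P(dQALY>0) %.2f\n",
              format(round(mean(x$draws$delta_cost)), big.mark = ","),
              mean(x$draws$delta_qalys), mean(x$draws$delta_qalys > 0)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective is the fraction of PSA draws with
#' positive net monetary benefit, `wtp * dQALY - dCost > 0`.
#'
#' @param psa a [sample_psa()] result.
#' @param wtp_grid willingness-to-pay thresholds in CA$ per QALY.
#' @return data frame of class `ceac_curve` with columns `wtp` and
#'   `probability_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 5000)) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$draws) > 0)
  p <- vapply(wtp_grid, function(l)
    mean(l * psa$draws$delta_qalys - psa$draws$delta_cost > 0), 0)
  out <- data.frame(wtp = wtp_grid, probability_cost_effective = p)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

# ---- one-way deterministic sensitivity --------------------------------------

#' Enumerate the uncertain parameters of the comparison
#'
#' Collects, across both arms: every non-death state cost (varied by its
#' relative half-width, +/-25% in the shipped model), every state utility
#' (varied by its printed absolute half-width, clipped to [0, 1]) and
#' every fixed transition probability (varied over its printed 95% CI, or
#' +/-25% relative when no CI is printed, clipped to [0, 100]).
#'
#' @param request an [analysis_request()].
#' @return data frame with columns `parameter`, `kind`, `state`/`from`/`to`
#'   and per-arm base/low/high values.
#' @export
param_table <- function(request = analysis_request()) {
  specs <- list(ada = build_arm("ada", request),
                no_ada = build_arm("no_ada", request))
  rows <- list()
  seen <- character(0)
  for (arm in names(specs)) {
    for (s in specs[[arm]]$states) {
      if (s$is_death) next
      key <- paste0("cost.", s$id)
      if (!key %in% seen && s$cost_per_cycle > 0) {
        seen <- c(seen, key)
        rows[[key]] <- data.frame(
          parameter = key, kind = "cost", state = s$id, from = NA, to = NA,
          base = s$cost_per_cycle,
          low = s$cost_per_cycle * (1 - s$cost_rel_halfwidth),
          high = s$cost_per_cycle * (1 + s$cost_rel_halfwidth))
      }
      key <- paste0("utility.", s$id)
      if (!key %in% seen && s$utility_halfwidth > 0) {
        seen <- c(seen, key)
        rows[[key]] <- data.frame(
          parameter = key, kind = "utility", state = s$id, from = NA, to = NA,
          base = s$annual_utility,
          low = max(0, s$annual_utility - s$utility_halfwidth),
          high = min(1, s$annual_utility + s$utility_halfwidth))
      }
    }
    for (row in specs[[arm]]$transitions) {
      for (e in row$entries) {
        if (e$kind != "fixed" || length(e$to) != 1L) next
        key <- paste0("prob.", row$from, ".", names(e$to))
        if (key %in% seen) next
        seen <- c(seen, key)
        lo <- if (!is.null(e$lo)) e$lo else max(0, e$value * 0.75)
        hi <- if (!is.null(e$hi)) e$hi else min(100, e$value * 1.25)
        rows[[key]] <- data.frame(
          parameter = key, kind = "probability", state = NA,
          from = row$from, to = names(e$to),
          base = e$value, low = lo, high = hi)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

arm_value <- function(spec, par) {
  if (par$kind == "cost") return(spec$states[[par$state]]$cost_per_cycle)
  if (par$kind == "utility") return(spec$states[[par$state]]$annual_utility)
  row <- spec$transitions[[par$from]]
  if (is.null(row)) return(NA_real_)
  for (e in row$entries)
    if (e$kind == "fixed" && identical(names(e$to), par$to)) return(e$value)
  NA_real_
}

override_for <- function(par, value) {
  switch(par$kind,
         cost = list(costs = stats::setNames(value, par$state)),
         utility = list(utilities = stats::setNames(value, par$state)),
         probability = list(probabilities =
                              list(list(from = par$from, to = par$to,
                                        value = value))))
}

icer_at <- function(request, par, value) {
  econ <- lapply(c("ada", "no_ada"), function(arm) {
    spec <- build_arm(arm, request)
    ab <- arm_value(spec, par)
    if (!is.na(ab)) {
      # scale the bound to the arm's own base so that arm-specific printed
      # values (e.g. the two pouchitis response probabilities) are varied
      # by the same relative amount
      v <- if (par$base == 0) value else ab * value / par$base
      spec <- apply_overrides(spec, override_for(par, v))
    }
    accumulate(run_cohort(spec))
  })
  compute_icer(econ[[1L]], econ[[2L]])
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs the full incremental analysis with the parameter at its lower
#' and upper bound (all other parameters at base). The override applies
#' to both arms. For arm-specific probabilities without a printed CI the
#' +/-25% variation is relative to each arm's own printed value.
#'
#' @param request an [analysis_request()].
#' @param parameter a parameter name from [param_table()], or a one-row
#'   subset of that table.
#' @return a `tornado_entry` list with the ICERs at both bounds and the
#'   spread.
#' @export
one_way <- function(request = analysis_request(), parameter) {
  tab <- param_table(request)
  if (is.character(parameter)) {
    par <- tab[tab$parameter == parameter, ]
    if (nrow(par) != 1L) stop("unknown parameter '", parameter, "'")
  } else par <- as.data.frame(parameter)

  lo <- icer_at(request, par, par$low)
  hi <- icer_at(request, par, par$high)
  spread <- if (is.na(lo$icer) || is.na(hi$icer)) NA_real_
            else abs(hi$icer - lo$icer)
  structure(list(parameter = par$parameter, kind = par$kind,
                 low_input = par$low, high_input = par$high,
                 icer_at_low = lo$icer, icer_at_high = hi$icer,
                 label_at_low = lo$label, label_at_high = hi$label,
                 spread = spread),
            class = "tornado_entry")
}

#' Tornado analysis: one-way sensitivity over all parameters
#'
#' @param request an [analysis_request()].
#' @param parameters optional subset of [param_table()] rows.
#' @return a `tornado_result`: data frame `entries` sorted by descending
#'   spread, plus `icer_min`/`icer_max` over all finite bound ICERs and
#'   the base ICER.
#' @export
tornado <- function(request = analysis_request(), parameters = NULL) {
  tab <- if (is.null(parameters)) param_table(request) else parameters
  base <- run_analysis(request)
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    e <- one_way(request, tab[i, ])
    data.frame(parameter = e$parameter, kind = e$kind,
               low_input = e$low_input, high_input = e$high_input,
               icer_at_low = e$icer_at_low, icer_at_high = e$icer_at_high,
               spread = e$spread)
  })
  entries <- do.call(rbind, entries)
  entries <- entries[order(-entries$spread), ]
  rownames(entries) <- NULL
  finite <- c(entries$icer_at_low, entries$icer_at_high)
  finite <- finite[is.finite(finite)]
  structure(list(entries = entries,
                 icer_min = min(finite), icer_max = max(finite),
                 base_icer = base$icer, request = request),
            class = "tornado_result")
}

#' @export
print.tornado_result <- function(x, ...) {
  cat("<tornado_result> base ICER",
      format(round(x$base_icer), big.mark = ","), "\n")
  cat(sprintf("  one-way ICER range: $%s - $%s\n",
              format(round(x$icer_min), big.mark = ","),
              format(round(x$icer_max), big.mark = ",")))
  print(utils::head(x$entries[, c("parameter", "icer_at_low",
                                  "icer_at_high", "spread")], 8))
  invisible(x)
}
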
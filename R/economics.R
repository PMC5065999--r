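# Discounted cost and QALY accounting, and incremental ratios.
#
# Accrual convention: state membership is counted at cycle start (no
# half-cycle correction), each cycle k = 0..H-1 accrues
#   cost:  occupancy[k] * cost_per_cycle * d(k)
#        + death-entry flow[k] * predecessor cost * d(k)   (one-time)
#   QALY:  occupancy[k] * annual_utility * cycle_length * d(k)
# with d(k) = (1 + r)^(-k * cycle_length).  Death states accrue nothing.

#' Present-value discount factor at a cycle
#'
#' @param cycle model cycle (0-based).
#' @param annual_rate annual discount rate (0.05 = 5%/year).
#' @param cycle_length_years cycle length in years.
#' @return `(1 + annual_rate)^(-cycle * cycle_length_years)`.
#' @export
discount_factor <- function(cycle, annual_rate, cycle_length_years = 0.25) {
  stopifnot(all(cycle >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-cycle * cycle_length_years)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Also returns per-state discounted exposures (occupancy-cycles and
#' death-entry flows, collapsed over tunnel copies), through which total
#' cost and QALYs are linear in the per-state costs and utilities — the
#' probabilistic sensitivity analysis re-prices these exposures instead
#' of re-running the cohort.
#'
#' @param trace a [run_cohort()] result.
#' @param spec the (unexpanded) [markov_spec()] the trace came from; used
#'   only for a consistency check and may be omitted.
#' @return an object of class `econ_result`: `total_cost`, `total_qalys`,
#'   `per_cycle` (data frame of discounted contributions), `exposure`
#'   (data frame with per-state discounted occupancy and death-flow).
#' @export
accumulate <- function(trace, spec = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  xspec <- trace$spec
  if (!is.null(spec) && !identical(spec$name, xspec$name))
    stop("trace was produced from model '", xspec$name, "', not '",
         spec$name, "'")
  H <- xspec$horizon_cycles
  len <- xspec$cycle_length_years
  d <- discount_factor(0:(H - 1L), xspec$annual_discount_rate, len)
  cost <- vapply(xspec$states, `[[`, 0, "cost_per_cycle")
  util <- vapply(xspec$states, `[[`, 0, "annual_utility")
  occ <- trace$occupancy[seq_len(H), , drop = FALSE]

  cycle_cost <- as.vector(occ %*% cost) * d +
    as.vector(trace$death_inflow %*% cost) * d
  cycle_qaly <- as.vector(occ %*% util) * len * d

  exp_occ <- as.vector(d %*% occ)                 # discounted occupancy-cycles
  exp_death <- as.vector(d %*% trace$death_inflow)
  grp <- trace$collapse[colnames(occ)]
  exposure <- data.frame(
    state = unname(grp), occupancy = exp_occ, death_flow = exp_death)
  exposure <- stats::aggregate(cbind(occupancy, death_flow) ~ state,
                               exposure, sum)

  structure(list(
    total_cost = sum(cycle_cost), total_qalys = sum(cycle_qaly),
    per_cycle = data.frame(cycle = 0:(H - 1L), discount = d,
                           cost = cycle_cost, qalys = cycle_qaly),
    exposure = exposure,
    horizon_cycles = H, cycle_length_years = len,
    model = xspec$name), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat("<econ_result>", x$model, "-", x$horizon_cycles, "cycles\n")
  cat(sprintf("  discounted cost : $%s\n",
              format(round(x$total_cost), big.mark = ",")))
  cat(sprintf("  discounted QALYs: %.3f\n", x$total_qalys))
  invisible(x)
}

#' Incremental cost-effectiveness ratio of two arms
#'
#' Deltas are intervention minus comparator. Dominance cases are
#' labelled, not divided: `"dominant"` (cheaper and at least as
#' effective), `"dominated"` (costlier and no more effective) and
#' `"undefined"` (equal effectiveness).
#'
#' @param intervention,comparator [accumulate()] results.
#' @return an object of class `icer_result`: `delta_cost`, `delta_qalys`,
#'   `icer`, `rounded_icer` (nearest $1,000, the reporting convention)
#'   and `label`.
#' @export
compute_icer <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qalys - comparator$total_qalys
  if (dq == 0) {
    label <- "undefined"; icer <- NA_real_
  } else if (dq > 0 && dc <= 0) {
    label <- "dominant"; icer <- dc / dq
  } else if (dq < 0) {
    label <- if (dc >= 0) "dominated" else "well-defined"
    icer <- if (dc >= 0) NA_real_ else dc / dq
  } else {
    label <- "well-defined"; icer <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qalys = dq, icer = icer,
                 rounded_icer = if (is.na(icer)) NA_real_
                                else round(icer / 1000) * 1000,
                 label = label,
                 intervention = intervention$model,
                 comparator = comparator$model),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer_result>", x$intervention, "vs", x$comparator, "\n")
  cat(sprintf("  delta cost : $%s\n", format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  delta QALYs: %.3f\n", x$delta_qalys))
  if (x$label %in% c("well-defined", "dominant"))
    cat(sprintf("  ICER: $%s/QALY (reported $%s)\n",
                format(round(x$icer), big.mark = ","),
                format(x$rounded_icer, big.mark = ",")))
  else cat("  ICER:", x$label, "\n")
  invisible(x)
}
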
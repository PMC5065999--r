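# ---- constructors -----------------------------------------------------------

#' Define a health state
#'
#' @param id short identifier used in transition rows.
#' @param label human-readable name (defaults to `id`).
#' @param cost_per_cycle CA$ accrued per 3-month cycle of occupancy.
#' @param annual_utility utility weight per year in `[0, 1]`.
#' @param is_death absorbing death state flag. Death accrues no recurring
#'   cost and zero utility; a one-time cost equal to the predecessor
#'   state's per-cycle cost is charged on the transition into death.
#' @param cost_rel_halfwidth relative half-width of the cost uncertainty
#'   interval (0.25 means +/-25%), used by the sensitivity analyses.
#' @param utility_halfwidth absolute half-width of the printed "(+/-x)"
#'   utility interval, read as a 95% interval.
#' @return a `health_state` list.
#' @export
health_state <- function(id, label = id, cost_per_cycle = 0,
                         annual_utility = 0, is_death = FALSE,
                         cost_rel_halfwidth = 0, utility_halfwidth = 0) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("state id must be a non-empty string")
  if (annual_utility < 0 || annual_utility > 1)
    stop("state '", id, "': annual_utility must lie in [0, 1]")
  if (cost_per_cycle < 0)
    stop("state '", id, "': cost_per_cycle must be non-negative")
  if (is_death && annual_utility != 0)
    stop("death state '", id, "' must have utility 0")
  structure(list(id = id, label = label, cost_per_cycle = cost_per_cycle,
                 annual_utility = annual_utility, is_death = is_death,
                 cost_rel_halfwidth = cost_rel_halfwidth,
                 utility_halfwidth = utility_halfwidth),
            class = "health_state")
}

# normalize an entry's `to` field into named weights summing to 1
normalize_to <- function(to) {
  if (is.character(to) && length(to) == 1L) return(stats::setNames(1, to))
  w <- unlist(to)
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("split transition targets must be named")
  if (abs(sum(w) - 1) > 1e-9) stop("split target weights must sum to 1")
  w
}

#' Build one outgoing transition entry
#'
#' Three kinds of entry make up a transition row: `fixed` (a printed
#' probability in percent, optionally with 95% CI bounds), `series` (a
#' probability read from a [retention_series()]) and `complement` (the
#' single "#" entry absorbing the remaining mass). `to` may be a single
#' state id or a named weight vector splitting the flow over several
#' states (used by the dose-escalation scenario).
#'
#' @param to target state id, or named weights summing to 1.
#' @param kind `"fixed"`, `"series"` or `"complement"`.
#' @param value probability in percent (fixed entries only).
#' @param lo,hi optional 95% CI bounds in percent (fixed entries only).
#' @param series name of the retention series (series entries only).
#' @param index clock for series lookup: `"cycle"` (model time) or
#'   `"residence"` (time in state).
#' @param offset integer added to the clock before lookup; an offset of 1
#'   marks a curve whose row 0 was already consumed by the entry
#'   transition into the state.
#' @param mode `"direct"` (curve value is the per-cycle maintenance
#'   probability) or `"conditional"` (curve is cumulative; use
#'   [retention_to_conditional()]).
#' @return a `transition_entry` list.
#' @export
transition_entry <- function(to, kind = c("fixed", "series", "complement"),
                             value = NULL, lo = NULL, hi = NULL,
                             series = NULL, index = c("cycle", "residence"),
                             offset = 0L, mode = c("direct", "conditional")) {
  kind <- match.arg(kind)
  e <- list(to = normalize_to(to), kind = kind)
  if (kind == "fixed") {
    if (is.null(value)) stop("fixed entry needs a value")
    if (value < 0 || value > 100)
      stop("fixed probability ", value, "% outside [0, 100]")
    if (!is.null(lo) && !is.null(hi) && !(lo <= value && value <= hi))
      stop("CI bounds (", lo, ", ", hi, ") do not bracket ", value)
    e$value <- value; e$lo <- lo; e$hi <- hi
  } else if (kind == "series") {
    if (is.null(series)) stop("series entry needs a series name")
    e$series <- series
    e$index <- match.arg(index)
    e$offset <- as.integer(offset)
    e$mode <- match.arg(mode)
  }
  structure(e, class = "transition_entry")
}

#' Build a transition row
#'
#' @param from source state id.
#' @param entries list of [transition_entry()] objects; exactly one must be
#'   a complement and at most one a series entry.
#' @param residence_clock if `TRUE` the row's series entry is indexed by
#'   time-in-state and the engine expands the state into tunnel copies.
#' @return a `transition_row` list.
#' @export
transition_row <- function(from, entries, residence_clock = FALSE) {
  kinds <- vapply(entries, `[[`, "", "kind")
  if (sum(kinds == "complement") != 1L)
    stop("row '", from, "': exactly one complement entry required, found ",
         sum(kinds == "complement"))
  if (sum(kinds == "series") > 1L)
    stop("row '", from, "': at most one series entry allowed")
  fixed_sum <- sum(vapply(entries[kinds == "fixed"], `[[`, 0, "value"))
  if (fixed_sum > 100 + 1e-9)
    stop("row '", from, "': fixed probabilities sum to ", fixed_sum,
         "% > 100%")
  structure(list(from = from, entries = entries,
                 residence_clock = isTRUE(residence_clock)),
            class = "transition_row")
}

#' Assemble a Markov cohort model specification
#'
#' @param states list of [health_state()] objects.
#' @param transitions list of [transition_row()] objects, one per
#'   non-death state.
#' @param series named list of [retention_series()] objects.
#' @param initial_distribution named vector of starting proportions
#'   (must sum to 1).
#' @param cycle_length_years cycle length in years (0.25 = 3 months).
#' @param annual_discount_rate annual discount rate for costs and QALYs.
#' @param horizon_cycles number of cycles to simulate.
#' @param name model name used in reports.
#' @return a validated object of class `markov_spec`.
#' @export
markov_spec <- function(states, transitions, series = list(),
                        initial_distribution,
                        cycle_length_years = 0.25,
                        annual_discount_rate = 0.05,
                        horizon_cycles = 40L,
                        name = "model") {
  ids <- vapply(states, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate state id: ", ids[duplicated(ids)][1L])
  names(states) <- ids
  names(transitions) <- vapply(transitions, `[[`, "", "from")
  spec <- structure(
    list(name = name, states = states, transitions = transitions,
         series = series,
         initial_distribution = unlist(initial_distribution),
         cycle_length_years = cycle_length_years,
         annual_discount_rate = annual_discount_rate,
         horizon_cycles = as.integer(horizon_cycles)),
    class = "markov_spec")
  validate_markov_spec(spec)
  spec
}

# internal constructor bypassing validation, for mechanical rewrites of
# already-validated specs (tunnel expansion)
new_markov_spec <- function(states, transitions, series, initial_distribution,
                            template) {
  names(states) <- vapply(states, `[[`, "", "id")
  names(transitions) <- vapply(transitions, `[[`, "", "from")
  structure(
    list(name = template$name, states = states, transitions = transitions,
         series = series, initial_distribution = unlist(initial_distribution),
         cycle_length_years = template$cycle_length_years,
         annual_discount_rate = template$annual_discount_rate,
         horizon_cycles = template$horizon_cycles),
    class = "markov_spec")
}

#' @export
print.markov_spec <- function(x, ...) {
  cat("<markov_spec>", x$name, "\n")
  cat(" ", length(x$states), "states,", length(x$transitions), "rows,",
      length(x$series), "retention series\n")
  cat("  horizon:", x$horizon_cycles, "cycles of",
      x$cycle_length_years, "years; discount",
      100 * x$annual_discount_rate, "%/yr\n")
  invisible(x)
}

# ---- validation -------------------------------------------------------------

state_ids <- function(spec) names(spec$states)

#' Validate a model specification
#'
#' Checks referential integrity (every transition target and series
#' reference is declared), the initial distribution, the uniqueness of
#' complement entries, probability ranges, death-state conventions
#' (no outgoing row, or a self-loop of probability 1), and that a death
#' state is reachable from the initial distribution.
#'
#' @param spec a [markov_spec()].
#' @return `spec`, invisibly; stops with an informative error otherwise.
#' @export
validate_markov_spec <- function(spec) {
  ids <- state_ids(spec)
  init <- spec$initial_distribution
  if (abs(sum(init) - 1) > 1e-9)
    stop("initial distribution sums to ", sum(init), ", not 1")
  bad <- setdiff(names(init), ids)
  if (length(bad)) stop("initial distribution names unknown state: ", bad[1L])

  is_death <- vapply(spec$states, `[[`, FALSE, "is_death")
  if (!any(is_death)) stop("model has no death state")

  edges <- list()
  for (row in spec$transitions) {
    if (!row$from %in% ids)
      stop("transition row from unknown state '", row$from, "'")
    for (e in row$entries) {
      tgt <- names(e$to)
      miss <- setdiff(tgt, ids)
      if (length(miss))
        stop("row '", row$from, "' references unknown state '", miss[1L], "'")
      if (e$kind == "series" && !e$series %in% names(spec$series))
        stop("row '", row$from, "' references unknown series '", e$series, "'")
      edges[[length(edges) + 1L]] <- cbind(row$from, tgt)
    }
    if (is_death[[row$from]]) {
      ok <- length(row$entries) == 1L &&
        identical(names(row$entries[[1L]]$to), row$from)
      if (!ok) stop("death state '", row$from, "' may only self-loop")
    }
  }
  no_row <- setdiff(ids[!is_death], names(spec$transitions))
  if (length(no_row))
    stop("non-death state '", no_row[1L], "' has no transition row")

  # death reachable from the initial support
  em <- do.call(rbind, edges)
  reach <- names(init)[init > 0]
  repeat {
    nxt <- union(reach, em[em[, 1L] %in% reach, 2L])
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (!any(is_death[reach]))
    stop("no death state is reachable from the initial distribution")
  invisible(spec)
}

# ---- row resolution ---------------------------------------------------------

series_probability <- function(entry, series_list, cycle, residence_time) {
  s <- series_list[[entry$series]]
  k <- if (entry$index == "residence") residence_time else cycle
  k <- k + entry$offset
  if (entry$mode == "direct") retention_at(s, k)
  else retention_to_conditional(s, min(k, 20L))
}

#' Resolve a transition row into probabilities at a given clock
#'
#' Fixed entries keep their printed values (converted from percent) and
#' a retention-series entry contributes the curve value at the row's
#' clock; the single complement entry absorbs the remaining mass. If the
#' fixed entries alone exceed 1 the row is inconsistent and resolution
#' stops with an error. A series value is clamped to the mass left after
#' the fixed entries (this can only occur where a curve exceeds one minus
#' the fixed branches, which in the shipped model happens only at clock
#' positions no patient can occupy). Split targets receive their weighted
#' share.
#'
#' @param row a [transition_row()].
#' @param cycle model cycle (0-based).
#' @param residence_time cycles already spent in the state (0-based).
#' @param series named list of [retention_series()] referenced by the row.
#' @return named vector of probabilities summing to 1.
#' @export
resolve_row <- function(row, cycle = 0L, residence_time = 0L,
                        series = list()) {
  stopifnot(cycle >= 0, residence_time >= 0)
  kinds <- vapply(row$entries, `[[`, "", "kind")
  fixed <- sum(vapply(row$entries[kinds == "fixed"], `[[`, 0, "value")) / 100
  if (fixed > 1 + 1e-12)
    stop("row '", row$from, "' at cycle ", cycle,
         ": fixed probabilities sum to ", signif(fixed, 6),
         " > 1; complement would be negative")
  has_series <- any(kinds == "series")
  if (has_series) {
    r <- series_probability(row$entries[[which(kinds == "series")]],
                            series, cycle, residence_time)
    stay <- min(r, 1 - fixed)
    comp <- 1 - fixed - stay
  } else {
    stay <- NULL
    comp <- 1 - fixed
  }
  comp <- max(comp, 0)

  out <- numeric(0)
  for (e in row$entries) {
    p <- switch(e$kind, fixed = e$value / 100, series = stay,
                complement = comp)
    w <- e$to * p
    for (nm in names(w)) out[nm] <- (if (nm %in% names(out)) out[nm] else 0) + w[[nm]]
  }
  out
}
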
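#' Cycle-indexed response-retention series
#'
#' A retention series holds the fraction of patients (in percent) still
#' maintaining clinical response at each 3-month cycle 0..20, with the
#' cycle-20 value used as a plateau for all later cycles. The shipped
#' ulcerative-colitis model carries four such series: the primary
#' adalimumab maintenance curve, the two chronic-pouchitis curves
#' (anti-TNF-naive and previously exposed) and the dose-escalated curve
#' borrowed from Crohn's disease outpatient data.
#'
#' @param name series identifier.
#' @param values numeric vector of length 21, percentages in (0, 100],
#'   non-increasing over cycles 0..20.
#' @param plateau_value value used for every cycle >= 20; defaults to (and
#'   must equal) the last element of `values`.
#' @return an object of class `retention_series`.
#' @export
retention_series <- function(name, values, plateau_value = NULL) {
  values <- as.numeric(values)
  if (length(values) != 21L)
    stop("retention series '", name, "' must have 21 values (cycles 0..20)")
  if (any(!is.finite(values)) || any(values <= 0) || any(values > 100))
    stop("retention series '", name, "' values must lie in (0, 100]")
  if (any(diff(values) > 1e-9))
    stop("retention series '", name, "' must be non-increasing in cycle")
  if (is.null(plateau_value)) plateau_value <- values[21L]
  if (abs(plateau_value - values[21L]) > 1e-9)
    stop("plateau_value must equal the cycle-20 entry")
  structure(list(name = name, values = values, plateau_value = plateau_value),
            class = "retention_series")
}

#' @export
print.retention_series <- function(x, ...) {
  cat("<retention_series>", x$name, "\n")
  cat("  cycle 0:", x$values[1L], " cycle 20+ (plateau):", x$plateau_value, "%\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (0.05 -> 0.1), matching the
#' convention used for the printed previously-exposed pouchitis curve,
#' which `round()`'s round-half-to-even does not reproduce.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Discount a retention series by a fixed relative reduction
#'
#' Applies the convention used for patients with chronic pouchitis who were
#' previously exposed to (and failed) adalimumab: every value of the naive
#' curve is reduced by `discount` (15% in the shipped model) and rounded to
#' one decimal, which reproduces the printed previously-exposed column from
#' the naive column at every cycle.
#'
#' @param series a [retention_series()].
#' @param discount relative reduction in `[0, 1)`.
#' @return a new `retention_series` named `<name>_discounted`.
#' @export
apply_retention_discount <- function(series, discount) {
  stopifnot(inherits(series, "retention_series"))
  if (!is.numeric(discount) || length(discount) != 1L ||
      discount < 0 || discount >= 1)
    stop("discount must be a single value in [0, 1)")
  retention_series(paste0(series$name, "_discounted"),
                   round_half_up(series$values * (1 - discount), 1L))
}

#' Retention value at a cycle (direct lookup)
#'
#' Returns the retention fraction (0..1) at cycle `k`, using the plateau
#' value for `k >= 20`. In the shipped model these values act directly as
#' per-cycle maintenance probabilities.
#'
#' @param series a [retention_series()].
#' @param k cycle index (0-based), non-negative.
#' @return probability in (0, 1].
#' @export
retention_at <- function(series, k) {
  stopifnot(inherits(series, "retention_series"), k >= 0)
  series$values[min(k, 20L) + 1L] / 100
}

#' Conditional one-cycle retention from a cumulative curve
#'
#' Reads the series as a survival curve and returns S(k+1)/S(k), the
#' probability of maintaining response for one more cycle given response
#' through cycle `k`. Beyond the plateau (`k >= 20`) the implied one-cycle
#' retention is 1. This is the standard survival-to-transition-probability
#' conversion; the engine's `conditional` series mode uses it.
#'
#' @param series a [retention_series()].
#' @param k cycle index (0-based), non-negative.
#' @return probability in (0, 1].
#' @export
retention_to_conditional <- function(series, k) {
  stopifnot(inherits(series, "retention_series"), length(k) == 1L, k >= 0)
  if (k >= 20) return(1)
  s_k <- series$values[k + 1L]
  if (s_k <= 0) stop("retention is zero at cycle ", k, "; ratio undefined")
  series$values[k + 2L] / s_k
}
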
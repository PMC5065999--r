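# Publication-style tables: the horizon x utility ICER grid with one-way
# ranges, scenario tables and CEAC tables, exportable as CSV or aligned
# text with identical numeric content.

fmt_dollar <- function(x) paste0("$", format(round(x / 1000) * 1000,
                                             big.mark = ",", trim = TRUE,
                                             scientific = FALSE))

#' ICER grid over horizons and utility variants, with one-way ranges
#'
#' Reproduces the layout of the headline results table: one row per time
#' horizon (5/10/15 years), one column per response-to-adalimumab utility
#' score (0.79/0.82), each cell `point (min-max)` where the range is the
#' one-way sensitivity envelope and every figure is rounded to the
#' nearest $1,000.
#'
#' @param scenario `"base"`, `"escalation"` or `"deescalation"`.
#' @param horizons time horizons in years.
#' @param utilities response-utility variants.
#' @param with_ranges compute one-way sensitivity ranges per cell (slower);
#'   when `FALSE` the range columns are `NA`.
#' @return data frame of class `icer_table` with numeric columns `icer`,
#'   `icer_min`, `icer_max` (rounded to $1,000) plus a formatted `cell`.
#' @export
make_table1 <- function(scenario = "base", horizons = c(5, 10, 15),
                        utilities = c(0.79, 0.82), with_ranges = TRUE) {
  cells <- list()
  for (u in utilities) for (h in horizons) {
    req <- analysis_request(h, u, scenario)
    res <- run_analysis(req)
    if (is.na(res$icer))
      stop("ICER undefined for horizon ", h, ", utility ", u)
    lo <- hi <- NA_real_
    if (with_ranges) {
      tor <- tornado(req)
      lo <- round(tor$icer_min / 1000) * 1000
      hi <- round(tor$icer_max / 1000) * 1000
    }
    cells[[length(cells) + 1L]] <- data.frame(
      horizon_years = h, response_utility = u,
      icer = res$rounded_icer, icer_min = lo, icer_max = hi,
      cell = if (with_ranges)
        sprintf("%s (%s-%s)", fmt_dollar(res$icer), fmt_dollar(lo),
                fmt_dollar(hi))
      else fmt_dollar(res$icer))
  }
  out <- do.call(rbind, cells)
  class(out) <- c("icer_table", "data.frame")
  out
}

#' Render an ICER table as aligned text
#'
#' @param x an [make_table1()] result.
#' @param ... unused.
#' @return the lines, invisibly; printed to the console.
#' @export
format_icer_table <- function(x, ...) {
  us <- sort(unique(x$response_utility))
  hs <- sort(unique(x$horizon_years))
  wide <- matrix("", length(hs), length(us),
                 dimnames = list(paste(hs, "years"), paste("u =", us)))
  for (i in seq_len(nrow(x)))
    wide[paste(x$horizon_years[i], "years"),
         paste("u =", x$response_utility[i])] <- x$cell[i]
  out <- utils::capture.output(print(as.data.frame(wide)))
  cat(out, sep = "\n")
  invisible(out)
}

#' Export a results data frame as CSV
#'
#' @param x data frame (ICER table, CEAC curve, tornado entries, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Arm-level economics summary for a request
#'
#' @param request an [analysis_request()].
#' @return data frame with one row per arm: discounted cost (rounded to
#'   $1,000 as reported) and QALYs (3 decimals), plus the unrounded
#'   values.
#' @export
arm_summary <- function(request = analysis_request()) {
  res <- run_analysis(request)
  rows <- lapply(c("ada", "no_ada"), function(a) {
    e <- attr(res, a)
    data.frame(arm = a, horizon_years = request$horizon_years,
               response_utility = request$response_utility,
               scenario = request$scenario,
               cost = e$total_cost, qalys = e$total_qalys,
               cost_reported = round(e$total_cost / 1000) * 1000,
               qalys_reported = round(e$total_qalys, 3))
  })
  do.call(rbind, rows)
}
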
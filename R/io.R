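# Reading and writing model specifications.
#
# Config schema (YAML or JSON, one document per arm):
#   name, cycle_length_years, annual_discount_rate, horizon_cycles
#   initial_distribution: {state_id: proportion, ...}
#   retention_series: {name: {values: [21 percentages]}, ...}
#   states: [{id, label, cost_per_cycle, annual_utility, is_death,
#             cost_rel_halfwidth, utility_halfwidth}, ...]
#   transitions: [{from, residence_clock, entries: [...]}, ...]
# with each entry one of
#   {to, p, ci: [lo, hi]}                                  fixed (percent)
#   {to, series, index: cycle|residence, offset, mode}     series-driven
#   {to, complement: true}                                 the "#" entry
# `to` is a state id or a {state_id: weight} map splitting the flow.

parse_entry <- function(e, from) {
  if (isTRUE(e$complement))
    return(transition_entry(e$to, "complement"))
  if (!is.null(e$series))
    return(transition_entry(e$to, "series", series = e$series,
                            index = if (is.null(e$index)) "cycle" else e$index,
                            offset = if (is.null(e$offset)) 0L else e$offset,
                            mode = if (is.null(e$mode)) "direct" else e$mode))
  if (is.null(e$p))
    stop("row '", from, "': entry is neither fixed, series nor complement")
  transition_entry(e$to, "fixed", value = e$p,
                   lo = if (is.null(e$ci)) NULL else e$ci[[1L]],
                   hi = if (is.null(e$ci)) NULL else e$ci[[2L]])
}

parse_state <- function(s) {
  health_state(
    id = s$id, label = if (is.null(s$label)) s$id else s$label,
    cost_per_cycle = if (is.null(s$cost_per_cycle)) 0 else s$cost_per_cycle,
    annual_utility = if (is.null(s$annual_utility)) 0 else s$annual_utility,
    is_death = isTRUE(s$is_death),
    cost_rel_halfwidth =
      if (is.null(s$cost_rel_halfwidth)) 0 else s$cost_rel_halfwidth,
    utility_halfwidth =
      if (is.null(s$utility_halfwidth)) 0 else s$utility_halfwidth)
}

#' Load and validate a model specification from a config file
#'
#' @param config_path path to a YAML (or JSON) model configuration.
#' @return a validated [markov_spec()].
#' @seealso [uc_fixture_path()] for the shipped ulcerative-colitis arms.
#' @export
load_model_spec <- function(config_path) {
  if (!file.exists(config_path)) stop("no such config file: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  series <- lapply(names(cfg$retention_series), function(nm)
    retention_series(nm, cfg$retention_series[[nm]]$values))
  names(series) <- names(cfg$retention_series)
  states <- lapply(cfg$states, parse_state)
  transitions <- lapply(cfg$transitions, function(tr)
    transition_row(tr$from,
                   lapply(tr$entries, parse_entry, from = tr$from),
                   residence_clock = isTRUE(tr$residence_clock)))
  markov_spec(
    states = states, transitions = transitions, series = series,
    initial_distribution = cfg$initial_distribution,
    cycle_length_years =
      if (is.null(cfg$cycle_length_years)) 0.25 else cfg$cycle_length_years,
    annual_discount_rate =
      if (is.null(cfg$annual_discount_rate)) 0.05 else cfg$annual_discount_rate,
    horizon_cycles =
      if (is.null(cfg$horizon_cycles)) 40L else cfg$horizon_cycles,
    name = if (is.null(cfg$name)) basename(config_path) else cfg$name)
}

entry_to_list <- function(e) {
  out <- list(to = as.list(e$to))
  if (e$kind == "fixed") {
    out$p <- e$value
    if (!is.null(e$lo)) out$ci <- c(e$lo, e$hi)
  } else if (e$kind == "series") {
    out$series <- e$series; out$index <- e$index
    out$offset <- e$offset; out$mode <- e$mode
  } else out$complement <- TRUE
  out
}

#' Serialize a model specification to a normalized list or JSON dump
#'
#' The dump is a semantic normal form suitable for diffing and audit:
#' reloading it (or the config it came from) yields an equal model.
#'
#' @param spec a [markov_spec()].
#' @param path optional file to write JSON to.
#' @return the normalized list, invisibly when `path` is given.
#' @export
serialize_model_spec <- function(spec, path = NULL) {
  out <- list(
    name = spec$name,
    cycle_length_years = spec$cycle_length_years,
    annual_discount_rate = spec$annual_discount_rate,
    horizon_cycles = spec$horizon_cycles,
    initial_distribution = as.list(spec$initial_distribution),
    retention_series = lapply(spec$series, function(s) list(values = s$values)),
    states = lapply(unname(spec$states), function(s) s[names(s)]),
    transitions = lapply(unname(spec$transitions), function(tr)
      list(from = tr$from, residence_clock = tr$residence_clock,
           entries = lapply(tr$entries, entry_to_list))))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
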
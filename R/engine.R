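# Time-inhomogeneous Markov cohort engine.
#
# Residence-time-dependent states are handled by tunnel expansion: a state
# whose row is indexed by time-in-state becomes a chain of cycle-indexed
# copies, all inbound flow entering copy 0.  Transition matrices are rebuilt
# each cycle (horizons of <= 60 cycles make caching pointless).

tunnel_id <- function(id, t) paste0(id, "..t", t)

#' Expand residence-clock states into tunnel chains
#'
#' Every state whose transition row carries `residence_clock = TRUE` is
#' replaced by 21 cycle-indexed copies (residence 0..19 plus a plateau
#' copy that is self-referential through the series plateau). Inbound
#' edges are redirected to copy 0; self-targeting entries chain to the
#' next copy; costs and utilities are inherited unchanged. A collapse map
#' from expanded to original ids is attached as attribute `"collapse"`.
#' Specs without residence-clock states are returned unchanged.
#'
#' @param spec a [markov_spec()].
#' @return an expanded `markov_spec`.
#' @export
expand_tunnels <- function(spec) {
  tun <- names(spec$transitions)[vapply(spec$transitions, `[[`, FALSE,
                                        "residence_clock")]
  if (!length(tun)) {
    attr(spec, "collapse") <- stats::setNames(state_ids(spec), state_ids(spec))
    return(spec)
  }

  redirect <- function(to) {   # send flows into a tunnel state to copy 0
    nm <- names(to)
    nm[nm %in% tun] <- tunnel_id(nm[nm %in% tun], 0L)
    stats::setNames(as.numeric(to), nm)
  }

  states <- list(); transitions <- list()
  collapse <- character(0)
  for (s in spec$states) {
    if (!s$id %in% tun) {
      states[[s$id]] <- s
      collapse[s$id] <- s$id
      next
    }
    for (t in 0:20) {
      cp <- s; cp$id <- tunnel_id(s$id, t)
      cp$label <- paste0(s$label, " [residence ", t, "]")
      states[[cp$id]] <- cp
      collapse[cp$id] <- s$id
    }
  }

  for (row in spec$transitions) {
    if (!row$from %in% tun) {
      row$entries <- lapply(row$entries, function(e) {
        e$to <- redirect(e$to); e
      })
      transitions[[row$from]] <- row
      next
    }
    for (t in 0:20) {
      entries <- lapply(row$entries, function(e) {
        nm <- names(e$to)
        self <- nm == row$from
        nm[self] <- tunnel_id(row$from, min(t + 1L, 20L))
        nm[!self & nm %in% tun] <- tunnel_id(nm[!self & nm %in% tun], 0L)
        e$to <- stats::setNames(as.numeric(e$to), nm)
        if (e$kind == "series") e$offset <- e$offset + t
        e
      })
      transitions[[tunnel_id(row$from, t)]] <-
        transition_row(tunnel_id(row$from, t), entries,
                       residence_clock = FALSE)
    }
  }

  init <- spec$initial_distribution
  names(init)[names(init) %in% tun] <-
    tunnel_id(names(init)[names(init) %in% tun], 0L)

  out <- new_markov_spec(states, transitions, spec$series, init, spec)
  attr(out, "collapse") <- collapse
  out
}

# Resolve all rows once; only rows holding a model-time ("cycle") indexed
# series entry change between cycles and need re-resolution.
resolve_static <- function(spec) {
  ids <- state_ids(spec)
  P <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  dynamic <- character(0)
  for (row in spec$transitions) {
    cyc <- any(vapply(row$entries, function(e)
      e$kind == "series" && e$index == "cycle", FALSE))
    if (cyc) dynamic <- c(dynamic, row$from)
    p <- resolve_row(row, cycle = 0L, series = spec$series)
    P[row$from, names(p)] <- p
  }
  death <- ids[vapply(spec$states, `[[`, FALSE, "is_death")]
  for (d in setdiff(death, names(spec$transitions))) P[d, d] <- 1
  list(P = P, dynamic = dynamic)
}

update_dynamic <- function(P, spec, dynamic, cycle) {
  for (s in dynamic) {
    p <- resolve_row(spec$transitions[[s]], cycle = cycle,
                     series = spec$series)
    P[s, ] <- 0
    P[s, names(p)] <- p
  }
  P
}

#' Transition matrix at one cycle
#'
#' @param spec an expanded [markov_spec()].
#' @param cycle model cycle (0-based).
#' @return a stochastic matrix with one row and column per state.
#' @export
transition_matrix <- function(spec, cycle) {
  ids <- state_ids(spec)
  P <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (row in spec$transitions) {
    p <- resolve_row(row, cycle = cycle, series = spec$series)
    P[row$from, names(p)] <- p
  }
  death <- ids[vapply(spec$states, `[[`, FALSE, "is_death")]
  for (d in setdiff(death, names(spec$transitions))) P[d, d] <- 1
  P
}

#' Run the cohort model
#'
#' Propagates the initial distribution through per-cycle transition
#' matrices, `occupancy[k + 1] = occupancy[k] %*% P(k)`, recording the
#' per-cycle flows into death states (needed for the transition-charged
#' one-time death cost). The model is tunnel-expanded automatically.
#'
#' @param spec a [markov_spec()].
#' @return an object of class `cohort_trace` with elements `occupancy`
#'   (matrix, `horizon_cycles + 1` rows), `death_inflow` (per-cycle flow
#'   into death by predecessor state), `collapse` (expanded id -> original
#'   id), and the expanded `spec`.
#' @export
run_cohort <- function(spec) {
  spec <- expand_tunnels(spec)
  ids <- state_ids(spec)
  H <- spec$horizon_cycles
  occ <- stats::setNames(numeric(length(ids)), ids)
  occ[names(spec$initial_distribution)] <- spec$initial_distribution
  occupancy <- matrix(0, H + 1L, length(ids), dimnames = list(NULL, ids))
  death_inflow <- matrix(0, H, length(ids), dimnames = list(NULL, ids))
  is_death <- vapply(spec$states, `[[`, FALSE, "is_death")
  occupancy[1L, ] <- occ
  rs <- resolve_static(spec)
  for (k in 0:(H - 1L)) {
    P <- if (length(rs$dynamic)) update_dynamic(rs$P, spec, rs$dynamic, k)
         else rs$P
    death_inflow[k + 1L, ] <- occ * rowSums(P[, is_death, drop = FALSE])
    death_inflow[k + 1L, is_death] <- 0   # staying dead is not a new death
    occ <- as.vector(occ %*% P)
    names(occ) <- ids
    occupancy[k + 2L, ] <- occ
  }
  structure(list(occupancy = occupancy, death_inflow = death_inflow,
                 collapse = attr(spec, "collapse"), spec = spec),
            class = "cohort_trace")
}

#' Collapse a trace over tunnel copies
#'
#' @param trace a [run_cohort()] result.
#' @return occupancy matrix with tunnel copies summed back into their
#'   original states.
#' @export
collapse_trace <- function(trace) {
  grp <- trace$collapse[colnames(trace$occupancy)]
  t(rowsum(t(trace$occupancy), grp))
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace>", x$spec$name, "-", nrow(x$occupancy) - 1L, "cycles,",
      ncol(x$occupancy), "expanded states\n")
  invisible(x)
}
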
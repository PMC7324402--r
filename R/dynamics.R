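#' Enumerate attractors and basins of a Boolean network
#'
#' Exhaustively follows the synchronous successor map over all `2^m` states.
#' Fixed points satisfy \eqn{S(T+1) = S(T)}; cycles are detected and flagged
#' too. The basin of an attractor is the set of states whose trajectory
#' reaches it (the attractor's own states included).
#'
#' @param net a `boolean_network` with `m <= 24`.
#' @return An `attractor_report`: list with `m`, `n_states`, `attractors`
#'   (each with `states` bit-strings in cycle order, `is_fixed_point`,
#'   `basin_size`, `basin_pct`), and `attractor_of`, the attractor index for
#'   every state id `0..2^m-1` (position `id + 1`). Attractors are ordered by
#'   decreasing basin size, ties by first state string.
#' @export
find_attractors <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  m <- net$m
  if (m > 24L) stopf("m = %d exceeds the exhaustive bound (24); sample trajectories instead", m)
  succ <- successor_map(net) + 1L        # 1-based
  n <- length(succ)
  # pointer doubling: term[s] = succ^(2^m)(s) lies on s's terminal cycle
  term <- succ
  for (d in seq_len(m)) term <- term[term]
  if (m == 0L) term <- succ
  cyc_seed <- unique(term)
  attractors <- list()
  rep_of <- integer(n)                    # cycle representative per seed node
  for (v in cyc_seed) {
    cyc <- v
    w <- succ[v]
    while (w != v) { cyc <- c(cyc, w); w <- succ[w] }
    r <- min(cyc)
    if (is.null(attractors[[as.character(r)]])) {
      ord <- c(which(cyc == r):length(cyc), seq_len(which(cyc == r) - 1L))
      attractors[[as.character(r)]] <- cyc[ord]
    }
    rep_of[v] <- r
  }
  rep_per_state <- rep_of[term]
  reps <- as.integer(names(attractors))
  basin <- vapply(reps, function(r) sum(rep_per_state == r), integer(1))
  strings <- lapply(attractors, function(cyc)
    vapply(cyc - 1L, function(id) state_to_string(id_to_state(id, m)), character(1)))
  ord <- order(-basin, vapply(strings, `[[`, character(1), 1L))
  atts <- lapply(seq_along(ord), function(j) {
    o <- ord[j]
    list(states = strings[[o]],
         is_fixed_point = length(strings[[o]]) == 1L,
         basin_size = basin[o],
         basin_pct = 100 * basin[o] / n)
  })
  att_index <- integer(n)
  for (j in seq_along(ord)) att_index[rep_per_state == reps[ord[j]]] <- j
  structure(list(m = m, n_states = n, attractors = atts, attractor_of = att_index),
            class = "attractor_report")
}

#' @export
print.attractor_report <- function(x, ...) {
  cat(sprintf("Attractor report: %d modules, %d states, %d attractor(s)\n",
              x$m, x$n_states, length(x$attractors)))
  for (a in x$attractors)
    cat(sprintf("  %s%s  basin %d (%.2f%%)\n",
                paste(a$states, collapse = " -> "),
                if (a$is_fixed_point) " [fixed point]" else " [cycle]",
                a$basin_size, a$basin_pct))
  invisible(x)
}

#' Full state-transition graph with per-attractor trees
#'
#' @param net a `boolean_network` with `m <= 24`.
#' @return A `transition_graph`: list with `m`, `successor` (1-based successor
#'   index per state id + 1), `attractor_of`, `depth` (steps to reach the
#'   attractor's states; 0 on the attractor itself) and the `attractor_report`.
#' @export
transition_graph <- function(net) {
  rep <- find_attractors(net)
  succ <- successor_map(net) + 1L
  n <- length(succ)
  on_att <- logical(n)
  for (a in rep$attractors)
    on_att[vapply(a$states, function(s) state_id(string_to_state(s)), integer(1)) + 1L] <- TRUE
  depth <- ifelse(on_att, 0L, NA_integer_)
  while (anyNA(depth)) {
    nd <- depth[succ] + 1L
    upd <- is.na(depth) & !is.na(nd)
    if (!any(upd)) stopf("internal error: unresolved depths")  # cannot happen
    depth[upd] <- nd[upd]
  }
  structure(list(m = rep$m, successor = succ, attractor_of = rep$attractor_of,
                 depth = depth, report = rep),
            class = "transition_graph")
}

#' Transition edges as a data frame
#'
#' Tree edges `state -> successor` for non-attractor states, plus attractor
#' internal edges, with the attractor index and depth of the source state.
#'
#' @param tg a `transition_graph`.
#' @return `data.frame(from, to, attractor, depth)` with bit-string states.
#' @export
as_edge_list <- function(tg) {
  stopifnot(inherits(tg, "transition_graph"))
  m <- tg$m
  ids <- seq_along(tg$successor) - 1L
  from <- vapply(ids, function(id) state_to_string(id_to_state(id, m)), character(1))
  data.frame(from = from, to = from[tg$successor],
             attractor = tg$attractor_of, depth = tg$depth,
             stringsAsFactors = FALSE)
}

#' Trajectory of the network from an initial state
#'
#' Follows synchronous updates from `s0` until a state repeats; the attractor
#' entry state is included once. With the physiological anterior-most state
#' as `s0` this is the major (developmental) trajectory.
#'
#' @param net a `boolean_network`.
#' @param s0 initial state (0/1 vector or bit-string).
#' @return Character vector of bit-strings, starting at `s0`.
#' @export
trajectory <- function(net, s0) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.character(s0)) s0 <- string_to_state(s0)
  s0 <- check_bits(s0)
  seen <- new.env(parent = emptyenv())
  path <- character(0)
  s <- s0
  repeat {
    key <- state_to_string(s)
    if (!is.null(seen[[key]])) break
    seen[[key]] <- TRUE
    path <- c(path, key)
    s <- bn_step(net, s)
  }
  path
}
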
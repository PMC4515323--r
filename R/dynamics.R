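#' Advance a network one synchronous step
#'
#' All nodes are updated simultaneously from the previous state. Clamped
#' nodes (deletions, environment nodes) are forced to their clamp level, and
#' capped nodes have rule outputs truncated at the cap.
#'
#' @param network A `discrete_network`.
#' @param state Integer activity vector (node order, or named).
#' @param clamps Optional named vector of `node = level` clamps, merged with
#'   any clamps already stored on the network.
#' @return The successor state (named integer vector).
#' @export
#' @examples
#' net <- swap_network()
#' step_synchronous(net, c(0, 1)) # (1, 0)
step_synchronous <- function(network, state, clamps = NULL) {
  state <- check_state(network, state)
  merged <- resolve_clamps(network, clamps)
  caps <- network$caps
  nxt <- state
  for (nm in network$nodes$name) {
    if (nm %in% names(merged)) {
      nxt[[nm]] <- merged[[nm]]
      next
    }
    r <- network$rules[[nm]]
    v <- evaluate_rule(r, unname(state[r$regulators]))
    if (nm %in% names(caps)) v <- min(v, caps[[nm]])
    nxt[[nm]] <- v
  }
  nxt
}

#' Advance a network one asynchronous step
#'
#' Three schemes are supported. `"single-random-node"` updates one uniformly
#' chosen node. The round schemes update every node once, each update seeing
#' the latest state: `"random-permutation-round"` in a freshly drawn random
#' order, `"fixed-order-round"` in declared node order.
#'
#' @inheritParams step_synchronous
#' @param scheme Update scheme name.
#' @param seed Integer seed making random schemes reproducible.
#' @return The successor state (named integer vector).
#' @export
step_asynchronous <- function(network, state,
                              scheme = c("single-random-node",
                                         "random-permutation-round",
                                         "fixed-order-round"),
                              seed = NULL, clamps = NULL) {
  scheme <- match.arg(scheme)
  state <- check_state(network, state)
  merged <- resolve_clamps(network, clamps)
  caps <- network$caps
  nm_all <- network$nodes$name
  if (!is.null(seed)) set.seed(seed)
  order <- switch(scheme,
    "single-random-node" = sample(nm_all, 1L),
    "random-permutation-round" = sample(nm_all),
    "fixed-order-round" = nm_all
  )
  for (nm in order) {
    if (nm %in% names(merged)) {
      state[[nm]] <- merged[[nm]]
      next
    }
    r <- network$rules[[nm]]
    v <- evaluate_rule(r, unname(state[r$regulators]))
    if (nm %in% names(caps)) v <- min(v, caps[[nm]])
    state[[nm]] <- v
  }
  state
}

#' Find the attractor reached from one initial condition
#'
#' Iterates the synchronous map, recording every visited state, until a
#' state repeats; the enclosed cycle is the attractor and the number of
#' steps before entering it is the transient length. Termination is
#' guaranteed: the state space is finite and the synchronous map is
#' deterministic.
#'
#' @inheritParams step_synchronous
#' @param state Initial condition.
#' @return A list of class `wdm_attractor_result` with elements `attractor`
#'   (a `wdm_attractor`: canonical cycle matrix and period) and
#'   `transient_length`.
#' @export
#' @examples
#' res <- find_attractor(swap_network(), c(0, 1))
#' res$attractor$period # 2
find_attractor <- function(network, state, clamps = NULL) {
  state <- check_state(network, state)
  ll <- net_lowlevel(network, clamps)
  state[ll$clamp >= 0L] <- ll$clamp[ll$clamp >= 0L]
  state <- pmin(state, ll$cap)
  res <- cpp_find_attractor(ll, unname(state))
  structure(
    list(attractor = new_attractor(res$cycle, network),
         transient_length = res$transient),
    class = "wdm_attractor_result"
  )
}

#' Specify a schedule of time-varying clamps
#'
#' Each row declares that `node` is clamped to `level` from step `time`
#' onward (until a later event re-clamps the same node). Two events at the
#' same time for the same node with different levels are contradictory and
#' rejected.
#'
#' @param time Integer vector of activation steps (0 = from the start).
#' @param node Character vector of node names.
#' @param level Integer vector of clamp levels.
#' @return A tibble of class `condition_schedule`.
#' @seealso [heat_shock_schedule()] for the standard temperature protocol.
#' @export
condition_schedule <- function(time, node, level) {
  sched <- tibble(time = as.integer(time), node = as.character(node),
                  level = as.integer(level))
  dup <- dplyr::group_by(sched, .data$time, .data$node)
  dup <- dplyr::filter(dup, dplyr::n_distinct(.data$level) > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("contradictory clamps at time %s for node %s",
                  dup$time[1L], dup$node[1L]))
  }
  sched <- dplyr::distinct(sched)
  class(sched) <- c("condition_schedule", class(sched))
  sched
}

#' Simulate a trajectory with optional time-varying clamps
#'
#' Runs `horizon` update steps from `state`, returning all `horizon + 1`
#' states including the initial one. Schedule events take effect at their
#' step: the state at that time and all later ones carry the clamp.
#'
#' @inheritParams step_synchronous
#' @param horizon Number of steps (>= 0).
#' @param schedule Optional [condition_schedule()].
#' @param scheme `"synchronous"` or one of the asynchronous schemes of
#'   [step_asynchronous()].
#' @param seed Seed for asynchronous schemes.
#' @return A tibble of class `wdm_trajectory`: column `time` then one column
#'   per node. The clamps applied at each step are recorded in the
#'   `clamps_applied` attribute.
#' @export
#' @examples
#' net <- swap_network()
#' simulate_trajectory(net, c(0, 1), horizon = 4)
simulate_trajectory <- function(network, state, horizon, schedule = NULL,
                                scheme = "synchronous", seed = NULL,
                                clamps = NULL) {
  stopifnot(horizon >= 0)
  state <- check_state(network, state)
  base_clamps <- resolve_clamps(network, clamps)
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "condition_schedule"))
  }
  clamps_at <- function(t) {
    cl <- base_clamps
    if (!is.null(schedule)) {
      act <- schedule[schedule$time <= t, , drop = FALSE]
      if (nrow(act) > 0L) {
        act <- act[order(act$time), , drop = FALSE]
        for (k in seq_len(nrow(act))) cl[[act$node[k]]] <- act$level[k]
      }
    }
    cl
  }
  n <- nrow(network$nodes)
  out <- matrix(NA_integer_, nrow = horizon + 1L, ncol = n,
                dimnames = list(NULL, network$nodes$name))
  applied <- vector("list", horizon + 1L)
  cl0 <- clamps_at(0L)
  if (length(cl0) > 0L) state[names(cl0)] <- cl0
  if (length(network$caps) > 0L) {
    state[names(network$caps)] <- pmin(state[names(network$caps)], network$caps)
  }
  out[1L, ] <- state
  applied[[1L]] <- cl0
  if (!is.null(seed)) set.seed(seed)
  if (identical(scheme, "synchronous")) {
    # fast path: constant-clamp segments between schedule events
    events <- if (is.null(schedule)) integer() else unique(schedule$time)
    breaks <- sort(unique(c(0L, events[events > 0L & events <= horizon],
                            horizon + 1L)))
    for (b in seq_len(length(breaks) - 1L)) {
      from <- breaks[b]
      to <- breaks[b + 1L] - 1L
      cl <- clamps_at(from)
      if (from > 0L) {
        # event step: advance once under the new clamps, then run the segment
        state <- step_synchronous(network, state, clamps = cl)
      }
      seg <- cpp_simulate_sync(net_lowlevel(network, cl), unname(state),
                               to - from)
      out[(from + 1L):(to + 1L), ] <- seg
      for (t in from:to) applied[[t + 1L]] <- cl
      state <- setNames(seg[nrow(seg), ], network$nodes$name)
    }
  } else {
    for (t in seq_len(horizon)) {
      cl <- clamps_at(t)
      state <- step_asynchronous(network, state, scheme = scheme, seed = NULL,
                                 clamps = cl)
      out[t + 1L, ] <- state
      applied[[t + 1L]] <- cl
    }
  }
  traj <- as_tibble(as.data.frame(out))
  traj <- dplyr::bind_cols(tibble(time = 0:horizon), traj)
  attr(traj, "clamps_applied") <- applied
  attr(traj, "scheme") <- scheme
  class(traj) <- c("wdm_trajectory", class(traj))
  traj
}

#' Two-node swap network
#'
#' The minimal oscillating fixture: two binary nodes copying each other
#' (`a' = b`, `b' = a`).
#'
#' @return A `discrete_network`.
#' @export
swap_network <- function() {
  nodes <- tibble(name = c("a", "b"), levels = c(2L, 2L), role = "")
  rules <- list(
    logic_rule("a", "b", 2L, 2L, c(0L, 1L)),
    logic_rule("b", "a", 2L, 2L, c(0L, 1L))
  )
  discrete_network(nodes, rules)
}
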
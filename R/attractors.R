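# attractor container: canonical cycle (period x n matrix), period, and
# basin statistics filled in by the landscape functions
new_attractor <- function(cycle, network, basin_count = NA_real_,
                          basin_fraction = NA_real_, basin_fraction_se = NA_real_) {
  cycle <- matrix(as.integer(cycle), nrow = nrow(cycle),
                  dimnames = list(NULL, network$nodes$name))
  structure(
    list(cycle = cycle, period = nrow(cycle), basin_count = basin_count,
         basin_fraction = basin_fraction, basin_fraction_se = basin_fraction_se),
    class = "wdm_attractor"
  )
}

#' @export
print.wdm_attractor <- function(x, ...) {
  cat(sprintf("<attractor: period %d", x$period))
  if (!is.na(x$basin_fraction)) cat(sprintf(", basin fraction %.4g", x$basin_fraction))
  cat(">\n")
  print(x$cycle)
  invisible(x)
}

#' Canonical form of a synchronous cycle
#'
#' Rotates a cycle so that its starting state has the minimal encoded index;
#' two cycles describe the same attractor exactly when their canonical forms
#' are equal. The input is validated to be a genuine synchronous cycle
#' (each state's successor is the next state, wrapping around).
#'
#' @param network A `discrete_network`.
#' @param cycle Matrix with one row per state (columns in node order), or a
#'   `wdm_attractor`.
#' @param clamps Optional clamps under which the cycle lives.
#' @return A `wdm_attractor` in canonical rotation.
#' @export
canonical_form <- function(network, cycle, clamps = NULL) {
  if (inherits(cycle, "wdm_attractor")) cycle <- cycle$cycle
  cycle <- as.matrix(cycle)
  L <- nrow(cycle)
  for (k in seq_len(L)) {
    nxt <- step_synchronous(network, cycle[k, ], clamps = clamps)
    expected <- cycle[if (k == L) 1L else k + 1L, ]
    if (!all(unname(nxt) == unname(expected))) {
      abort("not a valid synchronous cycle")
    }
  }
  enc <- apply(cycle, 1L, function(s) encode_state(network, s))
  arg <- which.min(enc)
  if (arg > 1L) cycle <- cycle[c(arg:L, seq_len(arg - 1L)), , drop = FALSE]
  new_attractor(cycle, network)
}

#' Enumerate the complete attractor landscape
#'
#' Assigns every admissible initial condition to its attractor by a
#' memoized-successor sweep over the full state space (each state's
#' successor is computed once) and reports exact basin sizes. Clamped
#' dimensions are collapsed, so the admissible space of a deletion strain is
#' the product of the free nodes' levels.
#'
#' @param network A `discrete_network`.
#' @param clamps Optional named clamps.
#' @param max_states Refuse exhaustive enumeration beyond this many states
#'   (default 1e6).
#' @return A `wdm_attractor_set` with `mode = "exhaustive"`; basin fractions
#'   are exact (`basin_count / n_initial_conditions`) and sum to one.
#' @export
#' @examples
#' aset <- enumerate_attractors_exhaustive(swap_network())
#' tidy(aset)
enumerate_attractors_exhaustive <- function(network, clamps = NULL,
                                            max_states = 1e6) {
  ll <- net_lowlevel(network, clamps)
  eff <- ifelse(ll$clamp >= 0L, 1, ll$cap + 1)
  omega <- prod(as.numeric(eff))
  if (omega > max_states) {
    abort(sprintf(
      "state space has %s admissible states, above the exhaustive cap of %s; use sample_attractors()",
      format(omega, big.mark = ","), format(max_states, big.mark = ",")
    ))
  }
  res <- cpp_enumerate_attractors(ll)
  attractors <- purrr::map2(res$cycles, res$basin_counts, function(cy, bc) {
    new_attractor(cy, network, basin_count = bc, basin_fraction = bc / omega)
  })
  new_attractor_set(attractors, network, mode = "exhaustive",
                    n_initial_conditions = omega, seed = NA_real_,
                    clamps = resolve_clamps(network, clamps))
}

#' Estimate the attractor landscape by sampling initial conditions
#'
#' Draws `n_samples` initial conditions uniformly (with replacement) from
#' the admissible state space, follows each to its attractor, and estimates
#' each basin fraction as `hits / n_samples` with its binomial standard
#' error. Fractions sum to one exactly.
#'
#' @param network A `discrete_network`.
#' @param n_samples Number of initial conditions (>= 1).
#' @param seed Integer seed for the sampling stream.
#' @param clamps Optional named clamps.
#' @return A `wdm_attractor_set` with `mode = "sampled"`.
#' @export
#' @examples
#' net <- generate_random_network(c(2, 2, 3), in_degree = 2, seed = 42)
#' tidy(sample_attractors(net, n_samples = 1000, seed = 7))
sample_attractors <- function(network, n_samples, seed, clamps = NULL) {
  stopifnot(n_samples >= 1)
  ll <- net_lowlevel(network, clamps)
  res <- cpp_sample_attractors(ll, as.integer(n_samples), as.numeric(seed))
  attractors <- purrr::map2(res$cycles, res$counts, function(cy, ct) {
    w <- ct / n_samples
    new_attractor(cy, network, basin_count = ct, basin_fraction = w,
                  basin_fraction_se = sqrt(w * (1 - w) / n_samples))
  })
  new_attractor_set(attractors, network, mode = "sampled",
                    n_initial_conditions = n_samples, seed = seed,
                    clamps = resolve_clamps(network, clamps))
}

new_attractor_set <- function(attractors, network, mode, n_initial_conditions,
                              seed, clamps) {
  # deterministic order: largest basin first, encoded start as tie-break
  key <- vapply(attractors, function(a) encode_state(network, a$cycle[1L, ]),
                numeric(1))
  w <- vapply(attractors, function(a) a$basin_fraction, numeric(1))
  attractors <- attractors[order(-w, key)]
  structure(
    list(attractors = attractors,
         mode = mode,
         n_initial_conditions = n_initial_conditions,
         seed = seed,
         clamps = clamps,
         nodes = network$nodes),
    class = "wdm_attractor_set"
  )
}

#' @export
print.wdm_attractor_set <- function(x, ...) {
  cat(sprintf("<attractor set: %d attractor(s), %s mode, n = %s>\n",
              length(x$attractors), x$mode,
              format(x$n_initial_conditions, big.mark = ",")))
  print(tidy(x))
  invisible(x)
}

#' Tidy an attractor set into one row per attractor
#'
#' @param x A `wdm_attractor_set`.
#' @param ... Unused.
#' @return A tibble with columns `attractor`, `period`, `basin_count`,
#'   `basin_fraction`, `basin_fraction_se`.
#' @method tidy wdm_attractor_set
#' @export
tidy.wdm_attractor_set <- function(x, ...) {
  tibble(
    attractor = seq_along(x$attractors),
    period = vapply(x$attractors, function(a) a$period, integer(1)),
    basin_count = vapply(x$attractors, function(a) as.numeric(a$basin_count), numeric(1)),
    basin_fraction = vapply(x$attractors, function(a) a$basin_fraction, numeric(1)),
    basin_fraction_se = vapply(x$attractors, function(a) a$basin_fraction_se, numeric(1))
  )
}

#' One-row summary of an attractor set
#'
#' @param x A `wdm_attractor_set`.
#' @param ... Unused.
#' @return A tibble with attractor count, mode, number of initial
#'   conditions, and the maximum period.
#' @method glance wdm_attractor_set
#' @export
glance.wdm_attractor_set <- function(x, ...) {
  tibble(
    n_attractors = length(x$attractors),
    mode = x$mode,
    n_initial_conditions = x$n_initial_conditions,
    max_period = max(vapply(x$attractors, function(a) a$period, integer(1)))
  )
}
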
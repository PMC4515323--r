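#' Windowed average of node activities over one attractor
#'
#' Averages every node over exactly one period of the attractor cycle (the
#' window length equals the attractor period). For a fixed point this is the
#' fixed-point level itself.
#'
#' @param attractor A `wdm_attractor`.
#' @return A tibble with columns `node` and `activity` (real values in
#'   `[0, levels - 1]` per node).
#' @export
#' @examples
#' res <- find_attractor(swap_network(), c(0, 1))
#' windowed_average(res$attractor) # 0.5, 0.5
windowed_average <- function(attractor) {
  stopifnot(inherits(attractor, "wdm_attractor"))
  tibble(node = colnames(attractor$cycle),
         activity = unname(colMeans(attractor$cycle)))
}

#' Basin-weighted population average of node activities
#'
#' The population-level expression profile: each node's windowed average per
#' attractor, weighted by the fractional basin size of that attractor and
#' summed over the whole attractor set. No attractor is discarded. This is
#' the quantity compared with batch-culture expression measurements.
#'
#' @param attractor_set A `wdm_attractor_set` (exhaustive or sampled).
#' @return A tibble of class `wdm_profile` with columns `node`, `sigma`
#'   (the basin-weighted average) and `se` (sampling standard error of
#'   `sigma`; zero in exhaustive mode). Provenance (mode, n, seed) is kept
#'   in attributes.
#' @export
population_average <- function(attractor_set) {
  stopifnot(inherits(attractor_set, "wdm_attractor_set"))
  if (length(attractor_set$attractors) == 0L) {
    abort("empty attractor set")
  }
  A <- vapply(attractor_set$attractors,
              function(a) colMeans(a$cycle), numeric(nrow(attractor_set$nodes)))
  A <- matrix(A, nrow = nrow(attractor_set$nodes)) # nodes x attractors
  w <- vapply(attractor_set$attractors, function(a) a$basin_fraction, numeric(1))
  sigma <- drop(A %*% w)
  se <- if (identical(attractor_set$mode, "sampled")) {
    # multinomial sampling: variance of the per-draw windowed value
    second <- drop((A^2) %*% w)
    sqrt(pmax(second - sigma^2, 0) / attractor_set$n_initial_conditions)
  } else {
    rep(0, length(sigma))
  }
  out <- tibble(node = attractor_set$nodes$name, sigma = sigma, se = se)
  attr(out, "mode") <- attractor_set$mode
  attr(out, "n_initial_conditions") <- attractor_set$n_initial_conditions
  attr(out, "seed") <- attractor_set$seed
  attr(out, "levels") <- attractor_set$nodes$levels
  class(out) <- c("wdm_profile", class(out))
  out
}

#' Long-run per-node averages of a trajectory
#'
#' Means over a window of steps after a burn-in, the standard summary for
#' asynchronous runs where exact attractor identification is not attempted.
#'
#' @param trajectory A `wdm_trajectory` from [simulate_trajectory()].
#' @param burn_in Steps discarded from the start.
#' @param window Number of steps averaged after the burn-in.
#' @return A tibble with columns `node` and `activity`.
#' @export
long_run_average <- function(trajectory, burn_in, window) {
  stopifnot(inherits(trajectory, "wdm_trajectory"))
  n_states <- nrow(trajectory)
  if (window < 1L) abort("empty averaging window")
  if (burn_in + window > n_states) {
    abort(sprintf("burn_in + window (%d) exceeds trajectory length (%d)",
                  burn_in + window, n_states))
  }
  rows <- (burn_in + 1L):(burn_in + window)
  vals <- trajectory[rows, setdiff(names(trajectory), "time"), drop = FALSE]
  tibble(node = names(vals), activity = unname(colMeans(as.matrix(vals))))
}

#' Expression ratios relative to a reference strain and condition
#'
#' Normalizes one node's population averages across a panel of strain and
#' condition combinations so the reference entry (by convention the wild
#' type at optimal temperature) equals one.
#'
#' @param profiles A tibble with columns `strain`, `condition`, `node`,
#'   `sigma` (long format, as produced by [predict_panel()]).
#' @param node Node whose expression is normalized (default the HSE
#'   reporter).
#' @param reference Length-2 character vector `c(strain, condition)` naming
#'   the reference entry.
#' @param floor Optional additive pseudo-floor applied to numerator and
#'   denominator; `NULL` (default) errors when the reference average is
#'   zero, since the ratio is then undefined.
#' @return A tibble with columns `strain`, `condition`, `sigma`, `ratio`.
#' @export
expression_ratio <- function(profiles, node = "HSE",
                             reference = c("WT", "25C"), floor = NULL) {
  stopifnot(all(c("strain", "condition", "node", "sigma") %in% names(profiles)))
  sub <- profiles[profiles$node == node, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("node '%s' absent from profiles", node))
  ref <- sub[sub$strain == reference[1L] & sub$condition == reference[2L], ]
  if (nrow(ref) != 1L) {
    abort(sprintf("reference (%s, %s) absent from profiles",
                  reference[1L], reference[2L]))
  }
  denom <- ref$sigma
  offset <- 0
  if (denom == 0) {
    if (is.null(floor)) {
      abort(paste0(
        "reference population average is zero; the ratio is undefined. ",
        "Supply `floor` to use an additive pseudo-floor."
      ))
    }
    offset <- floor
    denom <- denom + floor
  }
  tibble(strain = sub$strain, condition = sub$condition, sigma = sub$sigma,
         ratio = (sub$sigma + offset) / denom)
}
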
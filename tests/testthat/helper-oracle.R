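# Brute-force attractor-landscape oracle, independent of the package's
# simulation kernels: builds the full synchronous transition map by direct
# (vectorised) rule-table lookup over every admissible state, then extracts
# cycles by pointer doubling.  Tractable for state spaces up to ~10^5.
oracle_landscape <- function(network, clamps = NULL) {
  nm <- network$nodes$name
  lv <- network$nodes$levels
  n <- length(lv)
  merged <- network$clamps
  if (!is.null(clamps)) merged[names(clamps)] <- as.integer(unlist(clamps))
  clamp <- rep(-1L, n)
  if (length(merged) > 0L) clamp[match(names(merged), nm)] <- merged
  cap <- lv - 1L
  if (length(network$caps) > 0L) {
    cap[match(names(network$caps), nm)] <- as.integer(network$caps)
  }
  eff <- ifelse(clamp >= 0L, 1L, cap + 1L)
  omega <- prod(eff)
  stopifnot(omega <= 2e5)
  place_eff <- cumprod(c(1, eff[-n]))
  idx0 <- 0:(omega - 1)

  # state matrix: actual node values for every admissible state
  S <- vapply(seq_len(n), function(i) {
    if (clamp[i] >= 0L) rep(clamp[i], omega)
    else (idx0 %/% place_eff[i]) %% eff[i]
  }, numeric(omega))
  S <- matrix(S, nrow = omega)

  # successor values, per node, straight from the rule tables
  V <- matrix(0, nrow = omega, ncol = n)
  for (i in seq_len(n)) {
    if (clamp[i] >= 0L) {
      V[, i] <- clamp[i]
      next
    }
    r <- network$rules[[nm[i]]]
    if (length(r$regulators) == 0L) {
      out <- rep(r$table[1L], omega)
    } else {
      ri <- match(r$regulators, nm)
      rplace <- cumprod(c(1, r$reg_levels[-length(r$reg_levels)]))
      out <- r$table[1 + as.vector(S[, ri, drop = FALSE] %*% rplace)]
    }
    V[, i] <- pmin(out, cap[i])
  }
  free <- clamp < 0L
  succ <- as.integer(1 + as.vector(V[, free, drop = FALSE] %*% place_eff[free]))

  # pointer doubling: map every state to a state on its cycle
  on_cycle_map <- succ
  for (k in 1:20) on_cycle_map <- on_cycle_map[on_cycle_map]

  full_place <- cumprod(c(1, lv[-n]))
  encode_full <- function(row) sum(S[row, ] * full_place)

  cyc_id <- integer(omega) # representative (min full encoding) per in-cycle state
  cycles <- list()
  periods <- integer(0)
  keys <- numeric(0)
  seen <- logical(omega)
  for (u in unique(on_cycle_map)) {
    if (seen[u]) next
    cyc <- u
    v <- succ[u]
    while (v != u) {
      cyc <- c(cyc, v)
      v <- succ[v]
    }
    enc <- vapply(cyc, encode_full, numeric(1))
    key <- min(enc)
    cycles[[length(cycles) + 1L]] <- cyc[order(enc)][1L] # min state, eff index
    periods <- c(periods, length(cyc))
    keys <- c(keys, key)
    seen[cyc] <- TRUE
    cyc_id[cyc] <- length(cycles)
  }
  assignment <- cyc_id[on_cycle_map]
  basin <- tabulate(assignment, nbins = length(cycles))
  in_cycle <- logical(omega)
  in_cycle[unlist_int(cycles_full(succ, cycles))] <- TRUE

  list(keys = keys, periods = periods, basin_counts = basin,
       assignment = assignment, succ = succ, in_cycle = in_cycle,
       S = S, omega = omega, full_place = full_place,
       eff = eff, place_eff = place_eff, clamp = clamp)
}

# expand each cycle representative into the full cycle (eff indices)
cycles_full <- function(succ, reps) {
  lapply(reps, function(u) {
    cyc <- u
    v <- succ[u]
    while (v != u) {
      cyc <- c(cyc, v)
      v <- succ[v]
    }
    cyc
  })
}

unlist_int <- function(x) as.integer(unlist(x))

# transient length from one admissible state (eff index, 1-based)
oracle_transient <- function(orc, eff_index) {
  steps <- 0L
  v <- eff_index
  while (!orc$in_cycle[v]) {
    v <- orc$succ[v]
    steps <- steps + 1L
  }
  steps
}

# canonical keys (min full-space encoding over the cycle) of a package
# attractor set, for comparison against oracle keys
attractor_keys <- function(aset, network) {
  vapply(aset$attractors, function(a) {
    min(apply(a$cycle, 1L, function(s) encode_state(network, s)))
  }, numeric(1))
}

# deterministic small random fixture with bounded state space
random_fixture <- function(i, max_omega = 20000) {
  set.seed(i)
  repeat {
    n <- sample(3:6, 1L)
    lvls <- sample(2:4, n, replace = TRUE)
    if (prod(lvls) <= max_omega) break
  }
  in_deg <- sample.int(min(3L, n), 1L)
  generate_random_network(lvls, in_degree = in_deg, seed = i + 1000L)
}
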
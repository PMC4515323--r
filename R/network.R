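#' Create a logical rule for one node
#'
#' A rule maps every combination of its regulators' activity levels to an
#' output level of the target node. The table is stored flat in mixed-radix
#' order with the *first* regulator varying fastest (little-endian), the same
#' convention used by [encode_state()]. A rule with zero regulators is a
#' constant.
#'
#' @param target Name of the regulated node.
#' @param regulators Character vector of regulator node names (possibly
#'   empty). Order matters: it fixes the table layout.
#' @param reg_levels Integer vector of the regulators' level counts, aligned
#'   with `regulators`.
#' @param levels Level count of the target node; outputs lie in
#'   `0:(levels - 1)`.
#' @param table Integer vector of length `prod(reg_levels)` giving the output
#'   for every regulator-state combination.
#' @return An object of class `logic_rule`.
#' @seealso [rule_from_function()] to build the table from an R function,
#'   [evaluate_rule()] to apply it.
#' @export
#' @examples
#' # two binary inputs, logical OR
#' logic_rule("out", c("a", "b"), c(2L, 2L), 2L, c(0L, 1L, 1L, 1L))
logic_rule <- function(target, regulators, reg_levels, levels, table) {
  regulators <- as.character(regulators)
  reg_levels <- as.integer(reg_levels)
  levels <- as.integer(levels)
  table <- as.integer(table)
  if (length(regulators) != length(reg_levels)) {
    abort(sprintf("rule for node '%s': regulators and reg_levels lengths differ", target))
  }
  expected <- prod(reg_levels)
  if (length(table) != expected) {
    abort(sprintf(
      "rule for node '%s' is not total: table has %d entries, expected %d",
      target, length(table), expected
    ))
  }
  if (anyNA(table) || any(table < 0L) || any(table >= levels)) {
    abort(sprintf(
      "rule for node '%s': output levels must lie in 0..%d", target, levels - 1L
    ))
  }
  structure(
    list(target = target, regulators = regulators,
         reg_levels = reg_levels, levels = levels, table = table),
    class = "logic_rule"
  )
}

#' Build a rule table from an R function
#'
#' Enumerates every regulator-state combination (first regulator fastest) and
#' tabulates `fn`. This is the combinator entry point used to write rules as
#' threshold/min/max expressions while storing them as auditable tables.
#'
#' @inheritParams logic_rule
#' @param fn Function taking one integer argument per regulator (in order)
#'   and returning the output level.
#' @return A `logic_rule`.
#' @export
#' @examples
#' rule_from_function("out", c("a", "b"), c(2L, 3L), 4L,
#'                    function(a, b) min(a + b, 3L))
rule_from_function <- function(target, regulators, reg_levels, levels, fn) {
  combos <- level_grid(reg_levels)
  out <- if (nrow(combos) == 0L) {
    as.integer(fn())
  } else {
    as.integer(apply(combos, 1L, function(x) do.call(fn, as.list(as.integer(x)))))
  }
  logic_rule(target, regulators, reg_levels, levels, out)
}

# all regulator-state combinations, first column varying fastest;
# zero regulators yield a single empty combination
level_grid <- function(reg_levels) {
  if (length(reg_levels) == 0L) {
    return(matrix(integer(), nrow = 1L, ncol = 0L))
  }
  as.matrix(expand.grid(lapply(reg_levels, function(m) 0:(m - 1L)),
                        KEEP.OUT.ATTRS = FALSE))
}

#' Assemble and validate a multi-valued logical network
#'
#' @param nodes Data frame with columns `name`, `levels` (integer, >= 2) and
#'   optionally `role` (free-text annotation). Node order is preserved and
#'   fixes the state-encoding convention.
#' @param rules List of [logic_rule()] objects, exactly one per node.
#' @return An object of class `discrete_network` with elements `nodes`
#'   (tibble), `rules` (named list), and empty `clamps`/`caps` named integer
#'   vectors (see [apply_strain()]).
#' @export
#' @examples
#' nodes <- tibble::tibble(name = c("a", "b"), levels = c(2L, 2L))
#' rules <- list(
#'   logic_rule("a", "b", 2L, 2L, c(0L, 1L)),
#'   logic_rule("b", "a", 2L, 2L, c(0L, 1L))
#' )
#' net <- discrete_network(nodes, rules)
#' state_space_size(net)
discrete_network <- function(nodes, rules) {
  nodes <- as_tibble(nodes)
  if (!all(c("name", "levels") %in% names(nodes))) {
    abort("`nodes` needs columns 'name' and 'levels'")
  }
  if (!"role" %in% names(nodes)) nodes$role <- ""
  nodes$name <- as.character(nodes$name)
  nodes$levels <- as.integer(nodes$levels)
  dup <- nodes$name[duplicated(nodes$name)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate node name(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(nodes$levels < 2L)) {
    bad <- nodes$name[nodes$levels < 2L]
    abort(sprintf("node(s) with fewer than 2 levels: %s", paste(bad, collapse = ", ")))
  }
  targets <- vapply(rules, function(r) r$target, character(1))
  missing_rule <- setdiff(nodes$name, targets)
  if (length(missing_rule) > 0L) {
    abort(sprintf("missing rule for node(s): %s", paste(missing_rule, collapse = ", ")))
  }
  extra <- setdiff(targets, nodes$name)
  if (length(extra) > 0L) {
    abort(sprintf("rule(s) for unknown node(s): %s", paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(targets)) {
    abort(sprintf("multiple rules for node(s): %s",
                  paste(unique(targets[duplicated(targets)]), collapse = ", ")))
  }
  rules <- rules[match(nodes$name, targets)]
  names(rules) <- nodes$name
  lvl <- setNames(nodes$levels, nodes$name)
  for (r in rules) {
    unknown <- setdiff(r$regulators, nodes$name)
    if (length(unknown) > 0L) {
      abort(sprintf("rule for node '%s' names unknown regulator(s): %s",
                    r$target, paste(unknown, collapse = ", ")))
    }
    if (!identical(as.integer(lvl[r$regulators]), r$reg_levels)) {
      abort(sprintf("rule for node '%s': reg_levels disagree with network levels",
                    r$target))
    }
    if (r$levels != lvl[[r$target]]) {
      abort(sprintf("rule for node '%s': output levels disagree with node levels",
                    r$target))
    }
  }
  structure(
    list(nodes = nodes, rules = rules,
         clamps = setNames(integer(), character()),
         caps = setNames(integer(), character())),
    class = "discrete_network"
  )
}

#' Build a network from a parsed model definition
#'
#' Accepts the list structure produced by parsing a model-definition file
#' (see [read_model_file()]): `nodes` is a list of `(name, levels, role)`
#' records and `rules` a list of `(target, regulators, table)` records with
#' the table flat in first-regulator-fastest order.
#'
#' @param definition A list with elements `nodes` and `rules`.
#' @return A validated `discrete_network`.
#' @export
build_network <- function(definition) {
  if (!all(c("nodes", "rules") %in% names(definition))) {
    abort("model definition needs top-level 'nodes' and 'rules'")
  }
  nodes <- tibble(
    name = vapply(definition$nodes, function(x) as.character(x$name), character(1)),
    levels = vapply(definition$nodes, function(x) as.integer(x$levels), integer(1)),
    role = vapply(definition$nodes, function(x) {
      if (is.null(x$role)) "" else as.character(x$role)
    }, character(1))
  )
  lvl <- setNames(nodes$levels, nodes$name)
  rules <- lapply(definition$rules, function(r) {
    regs <- as.character(unlist(r$regulators))
    unknown <- setdiff(regs, nodes$name)
    if (length(unknown) > 0L) {
      abort(sprintf("rule for node '%s' names unknown regulator(s): %s",
                    r$target, paste(unknown, collapse = ", ")))
    }
    if (!r$target %in% nodes$name) {
      abort(sprintf("rule for unknown node '%s'", r$target))
    }
    logic_rule(r$target, regs, unname(lvl[regs]), lvl[[r$target]],
               as.integer(unlist(r$table)))
  })
  discrete_network(nodes, rules)
}

#' @export
print.discrete_network <- function(x, ...) {
  cat(sprintf("<discrete_network: %d nodes, %s states>\n",
              nrow(x$nodes), format(state_space_size(x), big.mark = ",")))
  k <- vapply(x$rules, function(r) length(r$regulators), integer(1))
  cat(sprintf("  levels: %s\n", paste(x$nodes$levels, collapse = " ")))
  cat(sprintf("  in-degree: min %d, max %d\n", min(k), max(k)))
  if (length(x$clamps) > 0L) {
    cat("  clamps:", paste(sprintf("%s=%d", names(x$clamps), x$clamps), collapse = ", "), "\n")
  }
  if (length(x$caps) > 0L) {
    cat("  caps:", paste(sprintf("%s<=%d", names(x$caps), x$caps), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of states in a network's state space
#'
#' The product of per-node level counts. Computed in double precision, which
#' is exact for counts below 2^53 (the bundled PKA network has about 4.3e9
#' states).
#'
#' @param network A `discrete_network`.
#' @return A numeric scalar holding the exact integer count.
#' @export
state_space_size <- function(network) {
  stopifnot(inherits(network, "discrete_network"))
  prod(as.numeric(network$nodes$levels))
}

#' Encode and decode network states
#'
#' States are integer vectors aligned with the network's node order. The
#' index is the little-endian mixed-radix number with the first node as the
#' least-significant digit: `index = sum_i state[i] * prod_{j<i} levels[j]`.
#' `encode_state()` and `decode_state()` are mutually inverse bijections
#' between states and `0:(state_space_size(network) - 1)`.
#'
#' @param network A `discrete_network`.
#' @param state Integer vector of node activity levels.
#' @param index State index in `[0, state_space_size(network))`.
#' @return `encode_state()` a numeric index; `decode_state()` a named integer
#'   state vector.
#' @export
#' @examples
#' net <- generate_random_network(c(2, 3, 6), in_degree = 1, seed = 1)
#' encode_state(net, c(1, 2, 5)) # 35
#' decode_state(net, 35)
encode_state <- function(network, state) {
  lv <- network$nodes$levels
  state <- check_state(network, state)
  sum(as.numeric(state) * cumprod(c(1, as.numeric(lv[-length(lv)]))))
}

#' @rdname encode_state
#' @export
decode_state <- function(network, index) {
  lv <- network$nodes$levels
  omega <- state_space_size(network)
  if (index < 0 || index >= omega) {
    abort(sprintf("index %s out of range [0, %s)", format(index), format(omega)))
  }
  s <- integer(length(lv))
  x <- as.numeric(index)
  for (i in seq_along(lv)) {
    s[i] <- as.integer(x %% lv[i])
    x <- (x - s[i]) / lv[i]
  }
  setNames(s, network$nodes$name)
}

#' Evaluate a logical rule on a regulator-state vector
#'
#' @param rule A `logic_rule`.
#' @param regulator_states Integer vector aligned with `rule$regulators`.
#' @return The output level (integer).
#' @export
evaluate_rule <- function(rule, regulator_states) {
  stopifnot(inherits(rule, "logic_rule"))
  regulator_states <- as.integer(regulator_states)
  if (length(regulator_states) != length(rule$regulators)) {
    abort(sprintf("rule for node '%s' takes %d regulator state(s), got %d",
                  rule$target, length(rule$regulators), length(regulator_states)))
  }
  if (any(regulator_states < 0L) || any(regulator_states >= rule$reg_levels)) {
    abort(sprintf("regulator state out of range for rule of node '%s'", rule$target))
  }
  if (length(regulator_states) == 0L) {
    return(rule$table[1L])
  }
  place <- cumprod(c(1L, rule$reg_levels[-length(rule$reg_levels)]))
  rule$table[1L + sum(regulator_states * place)]
}

# validate and normalize a state vector against the network
check_state <- function(network, state) {
  lv <- network$nodes$levels
  if (!is.null(names(state)) && all(network$nodes$name %in% names(state))) {
    state <- state[network$nodes$name]
  }
  state <- as.integer(state)
  if (length(state) != length(lv)) {
    abort(sprintf("state has %d entries, network has %d nodes",
                  length(state), length(lv)))
  }
  bad <- which(state < 0L | state >= lv)
  if (length(bad) > 0L) {
    abort(sprintf("state out of range for node(s): %s",
                  paste(network$nodes$name[bad], collapse = ", ")))
  }
  setNames(state, network$nodes$name)
}

# validate clamp/cap maps and merge with those stored on the network
resolve_clamps <- function(network, clamps = NULL) {
  merged <- network$clamps
  if (!is.null(clamps) && length(clamps) > 0L) {
    clamps <- unlist(clamps)
    unknown <- setdiff(names(clamps), network$nodes$name)
    if (length(unknown) > 0L) {
      abort(sprintf("clamp on unknown node(s): %s", paste(unknown, collapse = ", ")))
    }
    merged[names(clamps)] <- as.integer(clamps)
  }
  if (length(merged) > 0L) {
    lv <- setNames(network$nodes$levels, network$nodes$name)
    bad <- names(merged)[merged < 0L | merged >= lv[names(merged)]]
    if (length(bad) > 0L) {
      abort(sprintf("invalid clamp level for node(s): %s", paste(bad, collapse = ", ")))
    }
  }
  merged
}

# flat 0-based representation consumed by the C++ kernels
net_lowlevel <- function(network, clamps = NULL) {
  nm <- network$nodes$name
  lv <- network$nodes$levels
  merged_clamps <- resolve_clamps(network, clamps)
  clamp <- rep(-1L, length(nm))
  if (length(merged_clamps) > 0L) {
    clamp[match(names(merged_clamps), nm)] <- as.integer(merged_clamps)
  }
  cap <- lv - 1L
  if (length(network$caps) > 0L) {
    cap[match(names(network$caps), nm)] <- as.integer(network$caps)
  }
  list(
    levels = as.integer(lv),
    regs = lapply(network$rules, function(r) match(r$regulators, nm) - 1L),
    tables = lapply(network$rules, function(r) r$table),
    clamp = clamp,
    cap = cap
  )
}
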
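# ---------------------------------------------------------------------------
# The bundled 15-node PKA regulatory network (PKA-RN) of S. cerevisiae.
#
# Topology: the Ssa1/Ssa2 chaperones stabilise Cdc25, which drives the
# Ras2 -> Cyr1 -> cAMP cascade; cAMP relieves the inhibition that Bcy1
# imposes on the catalytic subunits Tpk1/Tpk2/Tpk3; Tpk2 (or, in its
# absence, Tpk1/Tpk3) activates the chaperones, closing a positive feedback
# loop.  Ssa1/Ssa2 and Repressor X (active only when Tpk2 is absent while
# Tpk1/Tpk3 are the sole catalytic subunits) repress the Hsf1 and Skn7
# transcription factors, which drive the HSE reporter (Hsf1 dominant, Skn7
# minor).  Heat shock is an auto-regulating environment node that lowers
# the effective activity of the chaperones.
#
# The exact rule tables are a reconstruction: level counts, the interaction
# sign structure and the qualitative strain phenotypes are fixed by the
# published genetics, and the tables below are the package's calibrated
# realisation of them (see the constraint suite in pka_constraints()).
# Tables are data, not code: write_model_file() emits them so users can
# substitute their own.
# ---------------------------------------------------------------------------

# activation ladder of the chaperone drive: the effective catalytic-subunit
# input is Tpk2 when present, else max(Tpk1, Tpk3) (mutual antagonism)
pka_chaperone_drive <- function(t1, t2, t3) {
  if (t2 >= 1L) t2 else max(t1, t3)
}

# repression weight of the chaperone pair on Hsf1; Ssa2 carries more weight
# than Ssa1 (SSA2 alone keeps wild-type repression, SSA1 alone does not)
pka_hsf1_repression <- function(s1, s2) {
  m <- matrix(c(0L, 2L, 2L, 4L,
                1L, 2L, 2L, 4L,
                1L, 2L, 2L, 4L,
                2L, 3L, 3L, 4L),
              nrow = 4L, byrow = TRUE)
  m[s1 + 1L, s2 + 1L]
}

pka_rule_functions <- function() {
  list(
    Cdc25 = function(s1, s2) c(1L, 4L, 5L, 5L, 5L, 5L, 5L)[s1 + s2 + 1L],
    Ras2  = function(c25) c(0L, 1L, 1L, 2L, 2L, 3L)[c25 + 1L],
    Cyr1  = function(r) r,
    cAMP  = function(cy) c(0L, 2L, 3L, 5L)[cy + 1L],
    Bcy1  = function(a) c(4L, 3L, 2L, 2L, 1L, 0L)[a + 1L],
    Tpk1  = function(a, b) min(5L, max(0L, a - b + 1L)),
    Tpk2  = function(a, b) min(5L, max(0L, a - b + 1L)),
    Tpk3  = function(a, b) min(5L, max(0L, a - b + 1L)),
    # chaperone synthesis follows the effective catalytic-subunit drive
    # (attenuated one level by heat shock, which raises the load of
    # alternative Hsp70 targets); decay is gradual, one level per step, so
    # a transient dip of the kinases does not instantly void the pool
    Ssa1  = function(t1, t2, t3, h, s) {
      d <- pka_chaperone_drive(t1, t2, t3)
      max(0L, c(0L, 0L, 2L, 2L, 3L, 3L)[d + 1L] - h, s - 1L)
    },
    Ssa2  = function(t1, t2, t3, h, s) {
      d <- pka_chaperone_drive(t1, t2, t3)
      max(0L, c(0L, 0L, 2L, 2L, 3L, 3L)[d + 1L] - h, s - 1L)
    },
    RepressorX = function(t1, t2, t3) {
      if (t2 == 0L && max(t1, t3) >= 1L) 1L else 0L
    },
    Hsf1  = function(s1, s2, x) max(0L, 5L - pka_hsf1_repression(s1, s2) - 3L * x),
    Skn7  = function(s1, s2, x) {
      base <- if (s1 + s2 == 0L) 2L else if (s1 + s2 == 1L) 1L else 0L
      max(0L, base - 2L * x)
    },
    # Hsf1 is the dominant activator; Skn7 binding adds a single increment
    HSE   = function(h, k) min(5L, c(0L, 1L, 1L, 2L, 3L, 4L)[h + 1L] + as.integer(k >= 1L)),
    HeatShock = function(h) h
  )
}

pka_node_table <- function() {
  tibble(
    name = c("Cdc25", "Ras2", "Cyr1", "cAMP", "Bcy1",
             "Tpk1", "Tpk2", "Tpk3", "Ssa1", "Ssa2",
             "RepressorX", "Hsf1", "Skn7", "HSE", "HeatShock"),
    levels = c(6L, 4L, 4L, 6L, 5L, 6L, 6L, 6L, 4L, 4L, 2L, 6L, 3L, 6L, 2L),
    role = c("GDP/GTP exchange factor", "small GTPase", "adenylate cyclase",
             "second messenger", "PKA regulatory subunit",
             "PKA catalytic subunit", "PKA catalytic subunit",
             "PKA catalytic subunit", "Hsp70 chaperone", "Hsp70 chaperone",
             "inferred repressor", "transcription factor",
             "transcription factor", "reporter", "environment")
  )
}

pka_regulators <- function() {
  list(
    Cdc25 = c("Ssa1", "Ssa2"),
    Ras2 = "Cdc25",
    Cyr1 = "Ras2",
    cAMP = "Cyr1",
    Bcy1 = "cAMP",
    Tpk1 = c("cAMP", "Bcy1"),
    Tpk2 = c("cAMP", "Bcy1"),
    Tpk3 = c("cAMP", "Bcy1"),
    Ssa1 = c("Tpk1", "Tpk2", "Tpk3", "HeatShock", "Ssa1"),
    Ssa2 = c("Tpk1", "Tpk2", "Tpk3", "HeatShock", "Ssa2"),
    RepressorX = c("Tpk1", "Tpk2", "Tpk3"),
    Hsf1 = c("Ssa1", "Ssa2", "RepressorX"),
    Skn7 = c("Ssa1", "Ssa2", "RepressorX"),
    HSE = c("Hsf1", "Skn7"),
    HeatShock = "HeatShock"
  )
}

#' Load the bundled PKA regulatory network
#'
#' Builds the 15-node multi-valued model of the yeast cAMP/PKA network with
#' the HSE reporter: two binary, one ternary, four four-valued, one
#' five-valued and seven six-valued nodes, for a state space of
#' 4,299,816,960 configurations.
#'
#' @return A `discrete_network`.
#' @seealso [pka_strain_library()], [predict_panel()], [pka_constraints()].
#' @export
#' @examples
#' net <- load_pka_model()
#' state_space_size(net) # 4,299,816,960
load_pka_model <- function() {
  nodes <- pka_node_table()
  lvl <- setNames(nodes$levels, nodes$name)
  regs <- pka_regulators()
  fns <- pka_rule_functions()
  rules <- lapply(nodes$name, function(nm) {
    rule_from_function(nm, regs[[nm]], unname(lvl[regs[[nm]]]), lvl[[nm]], fns[[nm]])
  })
  discrete_network(nodes, rules)
}

#' Level-collapsed binary variant of the PKA network
#'
#' Every node is binarized by thresholding its levels at `ceiling(m / 2)`:
#' a binary input maps to level 0 or the node maximum, and an output counts
#' as active when the multi-valued rule returns at least the threshold.
#' With 2^15 = 32,768 states the variant supports exhaustive
#' basin-of-attraction cross-checks of the qualitative strain phenotypes
#' that survive binarization (graded contrasts such as the heat-shock
#' attenuation of the chaperones collapse with the levels).
#'
#' @return A binary `discrete_network` over the same nodes and wiring.
#' @export
pka_reduced_model <- function() {
  full <- pka_node_table()
  lvl <- setNames(full$levels, full$name)
  regs <- pka_regulators()
  fns <- pka_rule_functions()
  nodes <- tibble(name = full$name, levels = 2L, role = full$role)
  rules <- lapply(full$name, function(nm) {
    rg <- regs[[nm]]
    thr <- ceiling(lvl[[nm]] / 2)
    rule_from_function(nm, rg, rep(2L, length(rg)), 2L, function(...) {
      b <- as.integer(c(...))
      rep_levels <- unname(lvl[rg] - 1L) * b
      as.integer(do.call(fns[[nm]], as.list(rep_levels)) >= thr)
    })
  })
  discrete_network(nodes, rules)
}

#' Specify a strain as deletions and level caps
#'
#' Deletions clamp nodes to level 0 for the whole dynamics (complete absence
#' of the gene product); level caps truncate a node's rule output at a
#' maximum, modelling hypomorphic alleles such as a transcription-factor
#' truncation that removes the heat-inducible activity increment.
#'
#' @param name Strain label.
#' @param deletions Character vector of deleted node names.
#' @param caps Named integer vector of `node = maximum level`.
#' @return A `strain_spec`.
#' @export
strain_spec <- function(name, deletions = character(), caps = integer()) {
  structure(list(name = name, deletions = as.character(deletions),
                 caps = caps), class = "strain_spec")
}

#' Strain library of the PKA expression panel
#'
#' The deletion and truncation strains whose HSE-dependent expression the
#' bundled model is calibrated against. Lower-case gene names denote
#' deletions (clamp to 0); `hsf1-dCTA` is the C-terminal truncation of Hsf1,
#' modelled as a level cap at the basal (non-heat-inducible) maximum;
#' `tpk2::TPK2 tpk3` carries a restored TPK2 gene in a tpk3 deletion
#' background.
#'
#' @return A tibble with columns `strain`, `deletions` (list-column) and
#'   `caps` (list-column of named integer vectors).
#' @export
pka_strain_library <- function() {
  hsf1_cap <- c(Hsf1 = 1L) # wild-type 25C steady-state Hsf1 level
  spec <- list(
    list("WT", character(), integer()),
    list("cdc25", "Cdc25", integer()),
    list("hsf1-dCTA", character(), hsf1_cap),
    list("hsf1-dCTA cdc25", "Cdc25", hsf1_cap),
    list("skn7", "Skn7", integer()),
    list("skn7 cdc25", c("Skn7", "Cdc25"), integer()),
    list("ras2", "Ras2", integer()),
    list("bcy1", "Bcy1", integer()),
    list("tpk1", "Tpk1", integer()),
    list("tpk2", "Tpk2", integer()),
    list("tpk3", "Tpk3", integer()),
    list("tpk1 tpk2", c("Tpk1", "Tpk2"), integer()),
    list("tpk1 tpk3", c("Tpk1", "Tpk3"), integer()),
    list("tpk2 tpk3", c("Tpk2", "Tpk3"), integer()),
    list("tpk2::TPK2 tpk3", "Tpk3", integer()),
    list("ssa1", "Ssa1", integer()),
    list("ssa2", "Ssa2", integer()),
    list("ssa1 tpk2", c("Ssa1", "Tpk2"), integer()),
    list("ssa2 tpk2", c("Ssa2", "Tpk2"), integer()),
    list("ssa1 ssa2", c("Ssa1", "Ssa2"), integer()),
    list("ssa1 ssa2 tpk2", c("Ssa1", "Ssa2", "Tpk2"), integer())
  )
  tibble(
    strain = vapply(spec, `[[`, character(1), 1L),
    deletions = lapply(spec, `[[`, 2L),
    caps = lapply(spec, `[[`, 3L)
  )
}

lookup_strain <- function(strain) {
  if (inherits(strain, "strain_spec")) return(strain)
  lib <- pka_strain_library()
  idx <- match(strain, lib$strain)
  if (is.na(idx)) {
    abort(sprintf("unknown strain '%s'; see pka_strain_library()", strain))
  }
  strain_spec(lib$strain[idx], lib$deletions[[idx]], lib$caps[[idx]])
}

#' Apply a strain's deletions and caps to a network
#'
#' Deleted nodes are clamped to 0 in every subsequent step, attractor and
#' trajectory; capped nodes have rule outputs (and sampled initial
#' conditions) truncated at the cap.
#'
#' @param network A `discrete_network`.
#' @param strain A [strain_spec()] or a strain name from
#'   [pka_strain_library()].
#' @return The network with clamps and caps set.
#' @export
#' @examples
#' net <- apply_strain(load_pka_model(), "cdc25")
#' net$clamps
apply_strain <- function(network, strain) {
  strain <- lookup_strain(strain)
  unknown <- setdiff(c(strain$deletions, names(strain$caps)), network$nodes$name)
  if (length(unknown) > 0L) {
    abort(sprintf("strain '%s' refers to unknown node(s): %s",
                  strain$name, paste(unknown, collapse = ", ")))
  }
  if (length(strain$deletions) > 0L) {
    network$clamps[strain$deletions] <- 0L
  }
  if (length(strain$caps) > 0L) {
    lv <- setNames(network$nodes$levels, network$nodes$name)
    bad <- names(strain$caps)[strain$caps >= lv[names(strain$caps)] - 0L |
                                strain$caps < 0L]
    if (any(strain$caps >= lv[names(strain$caps)])) {
      abort(sprintf("cap at or above node levels for: %s",
                    paste(bad, collapse = ", ")))
    }
    network$caps[names(strain$caps)] <- as.integer(strain$caps)
  }
  attr(network, "strain") <- strain$name
  network
}

#' Clamp the temperature condition
#'
#' `"25C"` clamps the heat-shock node to 0 for the whole simulation; `"39C"`
#' clamps it to 1 (once active it stays active, matching the node's positive
#' auto-regulation).
#'
#' @param network A `discrete_network` containing a `HeatShock` node.
#' @param condition `"25C"` or `"39C"`.
#' @return The network with the heat-shock clamp set.
#' @export
set_condition <- function(network, condition = c("25C", "39C")) {
  condition <- match.arg(condition)
  if (!"HeatShock" %in% network$nodes$name) {
    abort("network has no HeatShock node")
  }
  network$clamps["HeatShock"] <- if (condition == "39C") 1L else 0L
  attr(network, "condition") <- condition
  network
}

#' Temperature-switch schedule
#'
#' The standard heat-shock protocol: growth at optimal temperature, then a
#' shift to 39C at step `t0` (the heat-shock node turns on and stays on).
#'
#' @param t0 Step of the temperature upshift.
#' @return A [condition_schedule()].
#' @export
heat_shock_schedule <- function(t0) {
  condition_schedule(time = c(0L, as.integer(t0)),
                     node = c("HeatShock", "HeatShock"),
                     level = c(0L, 1L))
}

#' Draw a uniform random state of a network
#'
#' Uniform over the admissible space: clamped nodes at their clamp, capped
#' nodes uniform on `0:cap`, all others uniform over their levels.
#'
#' @param network A `discrete_network`.
#' @param seed Optional integer seed.
#' @return A named integer state vector.
#' @export
random_state <- function(network, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ll <- net_lowlevel(network)
  s <- vapply(seq_along(ll$levels), function(i) {
    if (ll$clamp[i] >= 0L) ll$clamp[i] else sample.int(ll$cap[i] + 1L, 1L) - 1L
  }, integer(1))
  setNames(s, network$nodes$name)
}

#' Predict the strain-by-condition expression panel
#'
#' For every strain and temperature condition, estimates the attractor
#' landscape (Monte-Carlo sampling of initial conditions by default, or
#' exhaustive enumeration for small networks), computes the basin-weighted
#' population average of every node, and normalizes the reporter to the
#' reference entry.
#'
#' @param strains Character vector of strain names (or list of
#'   [strain_spec()]); defaults to the full bundled library.
#' @param conditions Conditions to simulate (`"25C"`, `"39C"`).
#' @param n_samples Initial conditions sampled per strain and condition.
#' @param seed Base seed; each strain-condition combination receives its own
#'   deterministic sub-stream.
#' @param network The model (defaults to [load_pka_model()]).
#' @param reference `c(strain, condition)` entry whose HSE average is
#'   normalized to one.
#' @param exhaustive Enumerate instead of sample (only for small variants
#'   such as [pka_reduced_model()]).
#' @return A tibble of class `wdm_panel`: columns `strain`, `condition`,
#'   `node`, `sigma`, `se`, `ratio` (ratio is `NA` for nodes whose reference
#'   average is zero).
#' @export
predict_panel <- function(strains = pka_strain_library()$strain,
                          conditions = c("25C", "39C"),
                          n_samples = 1e5, seed = 1,
                          network = load_pka_model(),
                          reference = c("WT", "25C"),
                          exhaustive = FALSE) {
  specs <- lapply(strains, lookup_strain)
  combos <- tidyr::expand_grid(i = seq_along(specs), condition = conditions)
  rows <- purrr::pmap(combos, function(i, condition) {
    net <- set_condition(apply_strain(network, specs[[i]]), condition)
    aset <- if (exhaustive) {
      enumerate_attractors_exhaustive(net)
    } else {
      sub_seed <- as.numeric(seed) * 1009 + (i - 1L) * length(conditions) +
        match(condition, conditions)
      sample_attractors(net, n_samples = n_samples, seed = sub_seed)
    }
    prof <- population_average(aset)
    tibble(strain = specs[[i]]$name, condition = condition,
           node = prof$node, sigma = prof$sigma, se = prof$se)
  })
  panel <- dplyr::bind_rows(rows)
  ref <- panel[panel$strain == reference[1L] & panel$condition == reference[2L], ]
  if (nrow(ref) == 0L) {
    abort(sprintf("reference (%s, %s) not in panel", reference[1L], reference[2L]))
  }
  ref_sigma <- setNames(ref$sigma, ref$node)
  panel$ratio <- unname(ifelse(ref_sigma[panel$node] > 0,
                               panel$sigma / ref_sigma[panel$node], NA_real_))
  attr(panel, "reference") <- reference
  attr(panel, "n_samples") <- if (exhaustive) NA_real_ else n_samples
  attr(panel, "seed") <- if (exhaustive) NA_real_ else seed
  class(panel) <- c("wdm_panel", class(panel))
  panel
}

#' Replicated single-cell heat-shock trajectories
#'
#' Simulates synchronous trajectories from random initial conditions with a
#' temperature upshift at `t0` and averages them per time point, the
#' single-cell counterpart of the population panel.
#'
#' @param strain Strain name or [strain_spec()].
#' @param t0 Step of the temperature upshift.
#' @param horizon Total steps simulated.
#' @param n_cells Number of independent initial conditions averaged.
#' @param seed Integer seed.
#' @param network The model.
#' @return A tibble of class `wdm_trajectory_panel`: `time`, `node`,
#'   `activity` (mean over cells), `strain`.
#' @export
simulate_heat_shock_response <- function(strain, t0 = 30L, horizon = 150L,
                                         n_cells = 20L, seed = 1,
                                         network = load_pka_model()) {
  spec <- lookup_strain(strain)
  net <- apply_strain(network, spec)
  sched <- heat_shock_schedule(t0)
  acc <- NULL
  for (cell in seq_len(n_cells)) {
    init <- random_state(net, seed = as.integer(seed) + cell)
    traj <- simulate_trajectory(net, init, horizon = horizon, schedule = sched)
    m <- as.matrix(traj[, setdiff(names(traj), "time")])
    acc <- if (is.null(acc)) m else acc + m
  }
  acc <- acc / n_cells
  out <- as_tibble(as.data.frame(acc))
  out$time <- 0:horizon
  out <- tidyr::pivot_longer(out, -"time", names_to = "node",
                             values_to = "activity")
  out$strain <- spec$name
  attr(out, "t0") <- t0
  class(out) <- c("wdm_trajectory_panel", class(out))
  out
}
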
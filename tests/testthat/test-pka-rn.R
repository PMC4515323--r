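test_that("the bundled PKA network has the published structure", {
  net <- load_pka_model()
  expect_identical(state_space_size(net), 4299816960)
  expect_identical(nrow(net$nodes), 15L)
  expect_identical(sum(net$nodes$levels == 6L), 7L)
  expect_identical(sort(net$nodes$levels),
                   sort(c(2L, 2L, 3L, 4L, 4L, 4L, 4L, 5L, 6L, 6L, 6L, 6L, 6L, 6L, 6L)))
})

test_that("catalytic-subunit antagonism is wired into the chaperone and repressor rules", {
  net <- load_pka_model()
  ssa1 <- net$rules[["Ssa1"]]
  # with Tpk2 at maximum the chaperone is activated regardless of Tpk1/Tpk3
  for (t1 in c(0L, 5L)) {
    expect_gt(evaluate_rule(ssa1, c(t1, 5L, 0L, 0L, 0L)), 0)
  }
  repx <- net$rules[["RepressorX"]]
  # active exclusively when Tpk2 is absent while Tpk1/Tpk3 act as sole CS
  expect_identical(evaluate_rule(repx, c(5L, 0L, 0L)), 1L)
  expect_identical(evaluate_rule(repx, c(0L, 0L, 5L)), 1L)
  expect_identical(evaluate_rule(repx, c(5L, 5L, 5L)), 0L)
  expect_identical(evaluate_rule(repx, c(0L, 1L, 5L)), 0L)
  expect_identical(evaluate_rule(repx, c(0L, 0L, 0L)), 0L)
})

test_that("the heat-shock node is self-sustaining once active", {
  net <- load_pka_model() # no condition clamp: the node follows its own rule
  s <- random_state(net, seed = 2)
  s["HeatShock"] <- 1L
  for (k in 1:5) {
    s <- step_synchronous(net, s)
    expect_identical(s[["HeatShock"]], 1L)
  }
  s["HeatShock"] <- 0L
  s <- step_synchronous(net, s)
  expect_identical(s[["HeatShock"]], 0L)
})

test_that("strain deletions clamp nodes to zero in every attractor state", {
  net <- set_condition(apply_strain(load_pka_model(), "cdc25"), "25C")
  aset <- sample_attractors(net, n_samples = 300, seed = 5)
  for (a in aset$attractors) {
    expect_true(all(a$cycle[, "Cdc25"] == 0L))
  }
  # the wild type leaves the network unchanged
  wt <- apply_strain(load_pka_model(), "WT")
  expect_identical(length(wt$clamps), 0L)
  expect_identical(length(wt$caps), 0L)
  expect_error(apply_strain(load_pka_model(), strain_spec("x", "NoSuchNode")),
               "unknown node")
})

test_that("the Hsf1 truncation cap binds in every sampled attractor and trajectory", {
  net <- set_condition(apply_strain(load_pka_model(), "hsf1-dCTA"), "39C")
  aset <- sample_attractors(net, n_samples = 300, seed = 5)
  for (a in aset$attractors) {
    expect_true(all(a$cycle[, "Hsf1"] <= 1L))
  }
  traj <- simulate_trajectory(net, random_state(net, seed = 3), horizon = 50)
  expect_true(all(traj$Hsf1 <= 1L))
})

test_that("temperature conditions clamp the heat-shock node for the whole run", {
  net39 <- set_condition(load_pka_model(), "39C")
  expect_identical(net39$clamps[["HeatShock"]], 1L)
  aset <- sample_attractors(net39, n_samples = 200, seed = 1)
  for (a in aset$attractors) {
    expect_true(all(a$cycle[, "HeatShock"] == 1L))
  }
  net25 <- set_condition(load_pka_model(), "25C")
  expect_identical(net25$clamps[["HeatShock"]], 0L)
})

test_that("panel prediction is seed-deterministic and normalizes the reference to one", {
  p1 <- predict_panel(strains = c("WT", "cdc25"), n_samples = 2000, seed = 3)
  p2 <- predict_panel(strains = c("WT", "cdc25"), n_samples = 2000, seed = 3)
  expect_identical(p1$sigma, p2$sigma)
  expect_identical(p1$ratio[p1$strain == "WT" & p1$condition == "25C" &
                              p1$node == "HSE"], 1)
  expect_gt(p1$ratio[p1$strain == "cdc25" & p1$condition == "25C" &
                       p1$node == "HSE"], 1)
})

test_that("constraint evaluation demands a complete panel", {
  small <- predict_panel(strains = "WT", n_samples = 500, seed = 1)
  expect_error(evaluate_constraints(small), "missing strain")
})

test_that("a sign-flipped chaperone rule breaks the chaperone genetics", {
  # flip Ssa1/Ssa2: chaperones now activated when the kinase drive is LOW
  net <- load_pka_model()
  lvl <- setNames(net$nodes$levels, net$nodes$name)
  for (nm in c("Ssa1", "Ssa2")) {
    regs <- net$rules[[nm]]$regulators
    net$rules[[nm]] <- rule_from_function(nm, regs, unname(lvl[regs]), lvl[[nm]],
      function(t1, t2, t3, h, s) {
        d <- if (t2 >= 1L) t2 else max(t1, t3)
        max(0L, c(3L, 3L, 2L, 2L, 0L, 0L)[d + 1L] - h)
      })
  }
  sig <- function(strain) {
    nets <- set_condition(apply_strain(net, strain), "25C")
    prof <- population_average(sample_attractors(nets, 3000, seed = 4))
    prof$sigma[prof$node == "HSE"]
  }
  # removing both chaperones no longer derepresses the reporter strongly
  expect_lt(sig("ssa1 ssa2") / max(sig("WT"), 1e-9), 2)
})

test_that("the binarized variant supports exhaustive strain cross-checks", {
  red <- pka_reduced_model()
  expect_identical(state_space_size(red), 2^15)
  hse_avg <- function(strain, condition) {
    net <- set_condition(apply_strain(red, strain), condition)
    prof <- population_average(enumerate_attractors_exhaustive(net))
    prof$sigma[prof$node == "HSE"]
  }
  wt <- hse_avg("WT", "25C")
  # the qualitative deletion contrasts survive level collapsing
  expect_gt(hse_avg("cdc25", "25C"), wt)
  expect_gt(hse_avg("ras2", "25C"), wt)
  expect_gt(hse_avg("ssa1 ssa2", "25C"), wt)
  expect_lt(hse_avg("bcy1", "25C"), wt)
})
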
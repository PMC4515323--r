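test_that("synchronous stepping updates all nodes from the previous state", {
  net <- swap_network()
  expect_identical(unname(step_synchronous(net, c(0, 1))), c(1L, 0L))
  expect_identical(unname(step_synchronous(net, c(1, 1))), c(1L, 1L))

  # all-constant-0 rules send any state to the origin
  zero <- discrete_network(
    tibble::tibble(name = c("u", "v"), levels = c(3L, 2L)),
    list(logic_rule("u", character(), integer(), 3L, 0L),
         logic_rule("v", character(), integer(), 2L, 0L))
  )
  expect_identical(unname(step_synchronous(zero, c(2, 1))), c(0L, 0L))

  # clamped nodes are forced to the clamp level
  expect_identical(
    step_synchronous(net, c(0, 1), clamps = c(a = 0L))[["a"]], 0L
  )
  expect_error(step_synchronous(net, c(0, 1), clamps = c(a = 5L)),
               "invalid clamp")
})

test_that("asynchronous schemes update nodes against the evolving state", {
  net <- swap_network()
  # fixed order: node a copies b, then b copies the updated a
  expect_identical(
    unname(step_asynchronous(net, c(0, 1), "fixed-order-round")), c(1L, 1L)
  )
  # seeded schemes are reproducible
  s1 <- step_asynchronous(net, c(0, 1), "single-random-node", seed = 11)
  s2 <- step_asynchronous(net, c(0, 1), "single-random-node", seed = 11)
  expect_identical(s1, s2)
  p1 <- step_asynchronous(net, c(0, 1), "random-permutation-round", seed = 3)
  p2 <- step_asynchronous(net, c(0, 1), "random-permutation-round", seed = 3)
  expect_identical(p1, p2)
  expect_error(step_asynchronous(net, c(0, 1), "sweep"))
})

test_that("attractor search returns the exact cycle and transient", {
  net <- swap_network()
  res <- find_attractor(net, c(0, 1))
  expect_identical(res$attractor$period, 2L)
  expect_identical(res$transient_length, 0L)
  expect_setequal(apply(res$attractor$cycle, 1, paste, collapse = ""),
                  c("01", "10"))

  zero <- discrete_network(
    tibble::tibble(name = c("u", "v"), levels = c(3L, 2L)),
    list(logic_rule("u", character(), integer(), 3L, 0L),
         logic_rule("v", character(), integer(), 2L, 0L))
  )
  res0 <- find_attractor(zero, c(2, 1))
  expect_identical(res0$attractor$period, 1L)
  expect_lte(res0$transient_length, 1L)
  expect_identical(unname(res0$attractor$cycle[1, ]), c(0L, 0L))

  # the first attractor-cycle state follows the last transient state
  net42 <- generate_random_network(c(2, 2, 3), in_degree = 2, seed = 42)
  res42 <- find_attractor(net42, c(1, 1, 2))
  if (res42$transient_length > 0L) {
    traj <- simulate_trajectory(net42, c(1, 1, 2), res42$transient_length)
    last_transient <- unlist(traj[res42$transient_length, -1])
    nxt <- step_synchronous(net42, last_transient)
    expect_true(any(apply(res42$attractor$cycle, 1,
                          function(s) all(s == unname(nxt)))))
  }
})

test_that("attractor search matches the brute-force transition-map oracle", {
  net <- generate_random_network(c(2, 2, 3), in_degree = 2, seed = 42)
  orc <- oracle_landscape(net)
  for (idx in 0:11) {
    s <- decode_state(net, idx)
    res <- find_attractor(net, s)
    key <- min(apply(res$attractor$cycle, 1,
                     function(x) encode_state(net, x)))
    expect_identical(key, orc$keys[orc$assignment[idx + 1L]])
    expect_identical(res$attractor$period, orc$periods[orc$assignment[idx + 1L]])
    expect_identical(res$transient_length, oracle_transient(orc, idx + 1L))
  }
})

test_that("synchronous dynamics are deterministic", {
  net <- random_fixture(5)
  init <- decode_state(net, 7)
  r1 <- find_attractor(net, init)
  r2 <- find_attractor(net, init)
  expect_identical(r1$attractor$cycle, r2$attractor$cycle)
  expect_identical(r1$transient_length, r2$transient_length)
})

test_that("trajectories honour schedules and keep clamps at every step", {
  net <- load_pka_model()
  init <- random_state(net, seed = 9)

  # temperature switch: heat-shock node reads 1 at every step >= t0
  traj <- simulate_trajectory(net, init, horizon = 40,
                              schedule = heat_shock_schedule(15))
  expect_identical(traj$HeatShock[traj$time >= 15], rep(1L, 26))
  expect_identical(traj$HeatShock[traj$time < 15], rep(0L, 15))

  # constant 25C: the node stays off
  net25 <- set_condition(net, "25C")
  traj25 <- simulate_trajectory(net25, init, horizon = 20)
  expect_true(all(traj25$HeatShock == 0L))

  # deletion clamps hold over the whole trajectory
  netko <- apply_strain(net, "cdc25")
  trajko <- simulate_trajectory(set_condition(netko, "25C"), init, horizon = 20)
  expect_true(all(trajko$Cdc25 == 0L))

  # horizon 0 keeps only the initial state
  expect_identical(nrow(simulate_trajectory(net25, init, horizon = 0)), 1L)

  # contradictory clamps are rejected
  expect_error(condition_schedule(c(3, 3), c("HeatShock", "HeatShock"), c(0, 1)),
               "contradictory")
})

test_that("synchronous C++ fast path agrees with the R stepper", {
  net <- random_fixture(8)
  init <- decode_state(net, 3)
  traj <- simulate_trajectory(net, init, horizon = 15)
  s <- init
  for (t in 1:15) {
    s <- step_synchronous(net, s)
    expect_identical(unname(unlist(traj[t + 1L, -1])), unname(s))
  }
})
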
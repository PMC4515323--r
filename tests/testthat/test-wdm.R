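test_that("windowed averages take the mean over exactly one attractor period", {
  net <- swap_network()
  wa <- windowed_average(find_attractor(net, c(0, 1))$attractor)
  expect_identical(wa$activity, c(0.5, 0.5))

  # a fixed point averages to its own levels, exactly
  fp <- wdmnet:::new_attractor(rbind(c(2L, 0L, 5L)),
                               generate_random_network(c(3, 2, 6), 1, 1))
  expect_identical(windowed_average(fp)$activity, c(2, 0, 5))

  # a random fixture cycle equals the direct sum/period recomputation
  netr <- random_fixture(13)
  a <- find_attractor(netr, decode_state(netr, 5))$attractor
  expect_identical(windowed_average(a)$activity,
                   unname(colSums(a$cycle) / a$period))
})

test_that("population averages are basin-weighted convex combinations", {
  idnet <- discrete_network(
    tibble::tibble(name = "s", levels = 2L),
    list(logic_rule("s", "s", 2L, 2L, c(0L, 1L)))
  )
  prof <- population_average(enumerate_attractors_exhaustive(idnet))
  expect_identical(prof$sigma, 0.5)

  # a single attractor reproduces its windowed profile
  net <- swap_network()
  aset <- enumerate_attractors_exhaustive(net, clamps = NULL)
  single <- aset
  single$attractors <- aset$attractors[1]
  single$attractors[[1]]$basin_fraction <- 1
  p1 <- population_average(single)
  expect_identical(p1$sigma, windowed_average(single$attractors[[1]])$activity)

  # weighted three-attractor toy: 0.2*0 + 0.3*1 + 0.5*2 = 1.3
  tri <- discrete_network(
    tibble::tibble(name = "t", levels = 3L),
    list(logic_rule("t", "t", 3L, 3L, c(0L, 1L, 2L)))
  )
  aset3 <- enumerate_attractors_exhaustive(tri)
  levels3 <- vapply(aset3$attractors, function(a) a$cycle[1, 1], integer(1))
  ord <- match(0:2, levels3)
  aset3$attractors <- aset3$attractors[ord]
  for (k in 1:3) aset3$attractors[[k]]$basin_fraction <- c(0.2, 0.3, 0.5)[k]
  expect_identical(population_average(aset3)$sigma, 1.3)

  expect_error(population_average({
    empty <- aset
    empty$attractors <- list()
    empty
  }), "empty")
})

test_that("population averages respect node bounds and attractor-order invariance", {
  for (i in c(4, 21)) {
    net <- random_fixture(i)
    aset <- enumerate_attractors_exhaustive(net)
    prof <- population_average(aset)
    expect_true(all(prof$sigma >= 0))
    expect_true(all(prof$sigma <= net$nodes$levels - 1L))
    shuffled <- aset
    set.seed(1)
    shuffled$attractors <- sample(aset$attractors)
    expect_equal(population_average(shuffled)$sigma, prof$sigma)
  }
})

test_that("averaging windows that are integer multiples of the period are exact", {
  net <- swap_network()
  a <- find_attractor(net, c(0, 1))$attractor
  traj <- simulate_trajectory(net, c(0, 1), horizon = 40)
  for (c_mult in c(1, 3, 10)) {
    lr <- long_run_average(traj, burn_in = 0, window = 2 * c_mult)
    expect_identical(lr$activity, windowed_average(a)$activity)
  }
})

test_that("long-run trajectory averages handle constants, windows and errors", {
  net <- swap_network()
  traj <- simulate_trajectory(net, c(1, 1), horizon = 10) # fixed point
  lr <- long_run_average(traj, burn_in = 2, window = 5)
  expect_identical(lr$activity, c(1, 1))
  expect_error(long_run_average(traj, burn_in = 0, window = 0), "empty")
  expect_error(long_run_average(traj, burn_in = 10, window = 5), "exceeds")
})

test_that("expression ratios normalize to the reference entry", {
  profiles <- tibble::tibble(
    strain = c("WT", "WT", "mutA", "mutB"),
    condition = c("25C", "39C", "25C", "25C"),
    node = "HSE",
    sigma = c(1.5, 3.0, 3.0, 0.75)
  )
  rt <- expression_ratio(profiles, node = "HSE", reference = c("WT", "25C"))
  expect_identical(rt$ratio[rt$strain == "WT" & rt$condition == "25C"], 1)
  expect_identical(rt$ratio[rt$strain == "mutA"], 2)
  expect_identical(rt$ratio[rt$strain == "mutB"], 0.5)

  zeroed <- profiles
  zeroed$sigma[1] <- 0
  expect_error(expression_ratio(zeroed), "pseudo-floor")
  rz <- expression_ratio(zeroed, floor = 0.5)
  expect_identical(rz$ratio[rz$strain == "WT" & rz$condition == "25C"], 1)
})
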
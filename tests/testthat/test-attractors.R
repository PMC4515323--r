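test_that("canonical form starts at the minimal encoded state and is rotation-invariant", {
  net <- swap_network()
  # (1,0) encodes to 1, (0,1) to 2 under the little-endian convention
  can <- canonical_form(net, rbind(c(0L, 1L), c(1L, 0L)))
  expect_identical(unname(can$cycle[1, ]), c(1L, 0L))
  # a fixed point canonicalizes to itself
  fp <- canonical_form(net, rbind(c(1L, 1L)))
  expect_identical(unname(fp$cycle[1, ]), c(1L, 1L))
  expect_identical(fp$period, 1L)
  # all rotations of a cycle share one canonical form
  net4 <- discrete_network(
    tibble::tibble(name = c("p", "q"), levels = c(2L, 3L)),
    list(logic_rule("p", "q", 3L, 2L, c(1L, 0L, 0L)),
         logic_rule("q", "q", 3L, 3L, c(1L, 2L, 0L)))
  )
  cyc <- find_attractor(net4, c(0, 0))$attractor$cycle
  L <- nrow(cyc)
  for (k in seq_len(L)) {
    rot <- cyc[c(k:L, seq_len(L))[1:L], , drop = FALSE]
    expect_identical(canonical_form(net4, rot)$cycle, cyc)
  }
  # an arbitrary state list is rejected
  expect_error(canonical_form(net, rbind(c(0L, 0L), c(1L, 1L))), "not a valid")
})

test_that("exhaustive enumeration assigns every state and sums basins to the space size", {
  # single-node identity network: two fixed points, half the space each
  idnet <- discrete_network(
    tibble::tibble(name = "s", levels = 2L),
    list(logic_rule("s", "s", 2L, 2L, c(0L, 1L)))
  )
  aset <- enumerate_attractors_exhaustive(idnet)
  td <- tidy(aset)
  expect_identical(nrow(td), 2L)
  expect_identical(td$basin_fraction, c(0.5, 0.5))

  # all-constant-0 network with 36 states collapses to one basin
  zero36 <- discrete_network(
    tibble::tibble(name = c("u", "v", "w"), levels = c(2L, 3L, 6L)),
    list(logic_rule("u", character(), integer(), 2L, 0L),
         logic_rule("v", character(), integer(), 3L, 0L),
         logic_rule("w", character(), integer(), 6L, 0L))
  )
  td0 <- tidy(enumerate_attractors_exhaustive(zero36))
  expect_identical(nrow(td0), 1L)
  expect_identical(td0$basin_count, 36)
  expect_identical(td0$basin_fraction, 1)

  # refusal above the cap names the state-space size
  expect_error(enumerate_attractors_exhaustive(zero36, max_states = 10), "36")
})

test_that("exhaustive enumeration matches the brute-force oracle on random fixtures", {
  for (i in c(42, 7, 19)) {
    net <- random_fixture(i)
    aset <- enumerate_attractors_exhaustive(net)
    orc <- oracle_landscape(net)
    keys <- attractor_keys(aset, net)
    expect_setequal(keys, orc$keys)
    ord_pkg <- order(keys)
    ord_orc <- order(orc$keys)
    expect_identical(
      vapply(aset$attractors, function(a) a$period, integer(1))[ord_pkg],
      orc$periods[ord_orc]
    )
    expect_identical(
      vapply(aset$attractors, function(a) as.numeric(a$basin_count), numeric(1))[ord_pkg],
      as.numeric(orc$basin_counts[ord_orc])
    )
    expect_identical(sum(tidy(aset)$basin_count), state_space_size(net))
  }
})

test_that("sampled basin fractions estimate exhaustive fractions with binomial error", {
  idnet <- discrete_network(
    tibble::tibble(name = "s", levels = 2L),
    list(logic_rule("s", "s", 2L, 2L, c(0L, 1L)))
  )
  aset <- sample_attractors(idnet, n_samples = 10000, seed = 7)
  td <- tidy(aset)
  expect_identical(nrow(td), 2L)
  expect_true(all(abs(td$basin_fraction - 0.5) < 4 * sqrt(0.25 / 10000)))

  # a single sample yields one attractor with the whole weight
  one <- tidy(sample_attractors(idnet, n_samples = 1, seed = 1))
  expect_identical(nrow(one), 1L)
  expect_identical(one$basin_fraction, 1)

  # on enumerable fixtures the sampled fractions sit within 4 SE of exact
  for (i in c(42, 11)) {
    net <- random_fixture(i)
    exact <- enumerate_attractors_exhaustive(net)
    samp <- sample_attractors(net, n_samples = 20000, seed = i)
    ek <- attractor_keys(exact, net)
    sk <- attractor_keys(samp, net)
    expect_true(all(sk %in% ek)) # sampled attractors are genuine ones
    ew <- tidy(exact)$basin_fraction[match(sk, ek)]
    sw <- tidy(samp)$basin_fraction
    se <- pmax(tidy(samp)$basin_fraction_se, sqrt(ew * (1 - ew) / 20000))
    expect_true(all(abs(sw - ew) < 4 * pmax(se, 1e-4)))
  }
})

test_that("basin fractions sum to one exactly in both modes", {
  for (i in c(3, 42)) {
    net <- random_fixture(i)
    expect_identical(sum(tidy(enumerate_attractors_exhaustive(net))$basin_fraction), 1)
    expect_identical(sum(tidy(sample_attractors(net, 5000, seed = i))$basin_fraction), 1)
  }
})

test_that("attractors found from different sampling seeds deduplicate consistently", {
  net <- random_fixture(42)
  exact_keys <- attractor_keys(enumerate_attractors_exhaustive(net), net)
  k1 <- attractor_keys(sample_attractors(net, 3000, seed = 1), net)
  k2 <- attractor_keys(sample_attractors(net, 3000, seed = 2), net)
  expect_true(all(k1 %in% exact_keys))
  expect_true(all(k2 %in% exact_keys))
})
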
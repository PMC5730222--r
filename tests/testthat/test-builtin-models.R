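test_that("every factory output passes validation", {
  nets <- list(makeHomoreaction(), makeHeteroreaction(), makeCyclicChain(5),
               makeColloidalAggregation(6), makeEndosomeSwitch(),
               makeDelayedDegradation())
  for (net in nets) expect_length(validateNetwork(net), 0)
})

test_that("homoreaction model matches its printed operating point", {
  net <- makeHomoreaction()
  expect_equal(length(speciesIds(net)), 1L)
  expect_equal(nReactions(net), 2L)
  expect_equal(initialCounts(net)[["A"]], 25L)
  # a0 at n = 25 under the lumped-rate convention
  expect_equal(totalPropensity(net), 0.016 * 25 * 24 + 10)
  # n0 = 0: only the source channel is live
  net0 <- makeHomoreaction(n0 = 0)
  expect_equal(totalPropensity(net0), 10)
})

test_that("heteroreaction model matches its printed operating point", {
  net <- makeHeteroreaction()
  expect_equal(length(speciesIds(net)), 2L)
  expect_equal(totalPropensity(net), 0.04 * 25 * 1 + 1)
  # B appears on both sides of the bimolecular channel: conserved
  d <- reactionDelta(reactions(net)[[1]])
  expect_false("B" %in% names(d))
  # nb0 = 0 kills the death channel
  expect_equal(totalPropensity(makeHeteroreaction(nb0 = 0)), 1)
})

test_that("cyclic chain is N unimolecular conversions conserving total count", {
  expect_error(makeCyclicChain(1), "N >= 2")
  net <- makeCyclicChain(5)
  expect_equal(nReactions(net), 5L)
  for (rx in reactions(net)) {
    expect_length(rx@reactants, 1L)
    expect_length(rx@products, 1L)
  }
  expect_equal(totalPropensity(makeCyclicChain(3)), 3)
  # conservation along a simulated trajectory
  tr <- ssa(makeCyclicChain(6, n0 = 3), "pdm", tEnd = 50, dt = 5, seed = 11)
  expect_true(all(rowSums(tr@counts) == 18))
})

test_that("colloidal aggregation has floor(N^2/2) channels conserving mass", {
  expect_error(makeColloidalAggregation(1), "N >= 2")
  for (N in 2:16)
    expect_equal(nReactions(makeColloidalAggregation(N)), N^2 %/% 2L)
  net <- makeColloidalAggregation(2)
  expect_equal(nReactions(net), 2L)
  # every channel conserves sum(i * n_i)
  for (N in c(4L, 9L)) {
    net <- makeColloidalAggregation(N)
    w <- seq_len(N)
    for (rx in reactions(net)) {
      d <- reactionDelta(rx)
      idx <- as.integer(sub("^S", "", names(d)))
      expect_equal(sum(w[idx] * d), 0L)
    }
  }
  # and along a simulated trajectory
  tr <- ssa(makeColloidalAggregation(6, n0 = 2), "pdm", tEnd = 20, dt = 2,
            seed = 5)
  mass <- tr@counts %*% seq_len(6)
  expect_true(all(mass == mass[1]))
})

test_that("endosome switch model has 7 channels and converts units", {
  net <- makeEndosomeSwitch()
  expect_equal(nReactions(net), 7L)
  expect_equal(sort(speciesIds(net)), c("R5", "R7", "S0", "S1"))
  # 1.0 mol m^-3 in 4e-21 m^3 with Avogadro scaling
  expect_equal(initialCounts(net)[["R5"]],
               as.integer(round(1.0 * 4e-21 * 6.02214076e23)))
  expect_equal(initialCounts(net)[["R5"]], 2409L)
  expect_equal(initialCounts(net)[["R7"]], 0L)
  # S0 + S1 is invariant under every channel
  for (rx in reactions(net)) {
    d <- reactionDelta(rx)
    expect_equal(sum(d[intersect(names(d), c("S0", "S1"))]), 0L)
  }
  # and along a simulated trajectory
  tr <- ssa(net, "pdm", tEnd = 10, dt = 1, seed = 2)
  expect_true(all(tr@counts[, "S0"] + tr@counts[, "S1"] == 2409L))
  expect_error(endosomeParams(k1 = -1), "positive")
})

test_that("delayed-conversion toy degenerates to an undelayed channel at tau 0", {
  net <- makeDelayedDegradation(c = 2, tau = 0)
  expect_true(is.na(reactions(net)[[1]]@delay))
  net5 <- makeDelayedDegradation(c = 2, tau = 5, consuming = FALSE)
  expect_equal(reactions(net5)[[1]]@delay, 5)
  expect_false(reactions(net5)[[1]]@delayConsuming)
})

test_that("builtin model lookup resolves CLI-style names", {
  expect_equal(builtinModel("builtin:homoreaction")@name, "homoreaction")
  expect_equal(nReactions(builtinModel("cyclic_chain_N7")), 7L)
  expect_equal(nReactions(builtinModel("builtin:colloidal_aggregation_N6")), 18L)
  expect_error(builtinModel("builtin:nope"), "available")
})
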
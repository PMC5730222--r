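test_that("identical seeds give bit-identical trajectories", {
  net <- makeHomoreaction()
  for (method in c("dm", "pdm", "spdm", "pssacr", "dpdm")) {
    tr1 <- ssa(net, method, tEnd = 50, dt = 1, seed = 42)
    tr2 <- ssa(net, method, tEnd = 50, dt = 1, seed = 42)
    expect_identical(tr1@counts, tr2@counts)
    expect_identical(tr1@events, tr2@events)
    tr3 <- ssa(net, method, tEnd = 50, dt = 1, seed = 43)
    expect_false(identical(tr1@counts, tr3@counts))
  }
})

test_that("invalid method names are rejected with the valid list", {
  expect_error(ssa(makeHomoreaction(), "nrm", tEnd = 1, dt = 1),
               "dm, pdm, spdm, pssacr, dpdm, psrd")
})

test_that("pure death process matches the closed-form mean", {
  net <- reactionNetwork(data.frame(id = "A", amount = 100),
                         list(reaction(c(A = 1), NULL, rate = 1,
                                       specific = TRUE)))
  fs <- finalStates(net, "pdm", tEnd = 1, nSamples = 10000, seed = 9)
  a <- speciesCounts(fs, "A")
  # n(1) ~ Binomial(100, e^-1); 3-sigma Monte-Carlo band on the mean
  m <- 100 * exp(-1)
  sdSample <- sqrt(100 * exp(-1) * (1 - exp(-1)))
  expect_lt(abs(mean(a) - m), 3 * sdSample / sqrt(10000))
})

test_that("pure birth process is Poisson at the closed-form intensity", {
  net <- reactionNetwork(data.frame(id = "A", amount = 0),
                         list(reaction(NULL, c(A = 1), rate = 10,
                                       specific = TRUE)))
  fs <- finalStates(net, "pdm", tEnd = 1, nSamples = 20000, seed = 10)
  a <- speciesCounts(fs, "A")
  expect_lt(abs(mean(a) - 10), 3 * sqrt(10 / 20000))
  expect_gt(var(a) / mean(a), 0.95)
  expect_lt(var(a) / mean(a), 1.05)
})

test_that("the exhausted system freezes at its final state", {
  net <- reactionNetwork(data.frame(id = "A", amount = 5),
                         list(reaction(c(A = 1), NULL, rate = 50,
                                       specific = TRUE)))
  tr <- ssa(net, "pdm", tEnd = 10, dt = 1, seed = 1)
  expect_equal(unname(tr@counts[11, "A"]), 0L)
  expect_equal(tr@events, 5)
  expect_error(sampleEvents(net, "pdm", counts = c(A = 0)), "exhausted")
})

test_that("waiting times are exponential and single channels always fire", {
  net <- reactionNetwork(data.frame(id = "A", amount = 0),
                         list(reaction(NULL, c(A = 1), rate = 10,
                                       specific = TRUE)))
  ev <- sampleEvents(net, "pdm", nDraws = 10000, seed = 5)
  expect_true(all(ev$channel == 1L))
  expect_gt(stats::ks.test(ev$wait, stats::pexp, 10)$p.value, 0.01)
})

test_that("channel selection matches exact propensity ratios for all samplers", {
  # frozen heteroreaction at (25, 1): both channels have propensity 1.0
  het <- makeHeteroreaction()
  for (method in c("dm", "pdm", "spdm", "pssacr")) {
    ev <- sampleEvents(het, method, nDraws = 100000, seed = 21)
    expect_gt(chisqChannels(ev$channel, c(0.5, 0.5)), 0.01)
  }
  # frozen homoreaction at n = 25: propensities (9.6, 10)
  net <- makeHomoreaction()
  p <- c(9.6, 10) / 19.6
  freq <- list()
  for (method in c("dm", "pdm", "spdm", "pssacr")) {
    ev <- sampleEvents(net, method, nDraws = 100000, seed = 22)
    expect_gt(chisqChannels(ev$channel, p), 0.01)
    freq[[method]] <- tabulate(ev$channel, 2)
  }
  # pairwise agreement between the samplers
  pairs <- combn(names(freq), 2)
  for (j in seq_len(ncol(pairs))) {
    tab <- rbind(freq[[pairs[1, j]]], freq[[pairs[2, j]]])
    expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
  }
})

test_that("counts never go negative along trajectories", {
  for (method in c("dm", "pdm", "spdm", "pssacr")) {
    tr <- ssa(makeColloidalAggregation(6, n0 = 3), method, tEnd = 50,
              dt = 0.5, seed = 13)
    expect_true(all(tr@counts >= 0L))
  }
  tr <- ssa(makeHomoreaction(), "pssacr", tEnd = 500, dt = 1, seed = 14)
  expect_true(all(tr@counts >= 0L))
})

test_that("recorded state at t_k includes all events up to t_k", {
  # deterministic-rate check: a very fast source fills the first interval
  net <- reactionNetwork(data.frame(id = "A", amount = 0),
                         list(reaction(NULL, c(A = 1), rate = 1000,
                                       specific = TRUE)))
  tr <- ssa(net, "pdm", tEnd = 1, dt = 0.5, seed = 2)
  expect_equal(unname(tr@counts[1, "A"]), 0L)   # state at t = 0
  expect_gt(tr@counts[2, "A"], 300)             # ~500 events by t = 0.5
  expect_gt(tr@counts[3, "A"], tr@counts[2, "A"])
})
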
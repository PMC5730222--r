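test_that("network validation reports structural violations", {
  expect_length(validateNetwork(makeHomoreaction()), 0)
  expect_length(validateNetwork(makeHeteroreaction()), 0)

  # mutate past the constructor to exercise the report path
  net <- makeHeteroreaction()
  net@reactions[[1]]@reactants <- c(A = 1L, B = 1L, C = 1L)
  rep <- validateNetwork(net)
  expect_true(any(grepl("more than two distinct reactant", rep)))
  expect_true(any(grepl("unknown species C", rep)))

  net <- makeHeteroreaction()
  net@reactions[[1]]@reactants <- c(A = 2L, B = 2L)
  expect_true(any(grepl("two reactants with stoichiometry > 1",
                        validateNetwork(net))))

  net <- makeHomoreaction()
  net@reactions[[1]]@rate <- -1
  expect_true(any(grepl("positive", validateNetwork(net))))
})

test_that("reaction constructor enforces the A + N B reactant form", {
  expect_error(reaction(c(A = 1, B = 1, C = 1), NULL, rate = 1),
               "more than two distinct reactant")
  expect_error(reaction(c(A = 2, B = 2), NULL, rate = 1),
               "stoichiometry > 1")
  expect_s4_class(reaction(c(A = 1, B = 3), c(C = 1), rate = 1), "Reaction")
})

test_that("macroscopic rates convert to specific probability rates", {
  # order 1: no volume scaling
  expect_equal(specificRate(reaction(c(A = 1), NULL, rate = 1), 123, TRUE), 1)
  # pre-scaled lumped constants pass through untouched
  expect_equal(specificRate(reaction(NULL, c(A = 1), rate = 10,
                                     specific = TRUE), 123, TRUE), 10)
  # trimolecular S0 + 2 R7 at the endosome operating point
  rx <- reaction(c(S0 = 1, R7 = 2), c(S1 = 1, R7 = 2), rate = 100)
  omega <- 6.02214076e23 * 4e-21
  expect_equal(specificRate(rx, 4e-21, TRUE), 100 * 2 / omega^2)
  expect_equal(specificRate(rx, 4e-21, TRUE), 3.446737e-5, tolerance = 1e-5)
})

test_that("specific rates reproduce deterministic mass action in the dilute limit", {
  # a/Omega -> k * prod((n_i/Omega)^s_i) as counts grow at fixed concentration
  set.seed(42)
  for (case in list(c(A = 1), c(A = 2), c(A = 1, B = 1), c(A = 1, B = 2))) {
    k <- runif(1, 0.5, 5)
    rx <- reaction(case, NULL, rate = k)
    conc <- runif(length(case), 1, 3)
    names(conc) <- names(case)
    err <- vapply(c(1e3, 1e5, 1e7), function(omega) {
      cval <- specificRate(rx, omega, FALSE)
      counts <- round(conc * omega)
      a <- propensity(rx, counts, cval)
      macro <- k * prod((counts / omega)^case)
      abs(a / omega - macro) / macro
    }, numeric(1))
    if (err[1] > 1e-12) expect_lt(err[3], err[1])  # order 1 is exact already
    expect_lt(err[3], 1e-5)
  }
})

test_that("propensity is the specific rate times the reaction degeneracy", {
  rxAB <- reaction(c(A = 1, B = 1), c(B = 1), rate = 0.04, specific = TRUE)
  expect_equal(propensity(rxAB, c(A = 25, B = 1), 0.04), 1.0)
  rxAA <- reaction(c(A = 2), NULL, rate = 1, specific = TRUE)
  expect_equal(propensity(rxAA, c(A = 1), 1), 0)
  # degeneracy of S0 + 2 R7 equals the brute-force count of distinct
  # reactant combinations: one S0 molecule and an unordered R7 pair
  rx <- reaction(c(S0 = 1, R7 = 2), NULL, rate = 1, specific = TRUE)
  nCombos <- nrow(expand.grid(s = 1:3, pair = seq_len(ncol(combn(4, 2)))))
  expect_equal(propensity(rx, c(S0 = 3, R7 = 4), 0.5), 0.5 * nCombos)
  expect_equal(propensity(rx, c(S0 = 3, R7 = 4), 0.5), 9.0)
})

test_that("partial propensity factors the propensity over the pivot", {
  # source channel
  pp <- partialPropensity(reaction(NULL, c(A = 1), rate = 10, specific = TRUE),
                          c(A = 5), 10)
  expect_equal(pp$pivot, "source")
  expect_equal(pp$value, 10)
  # heterodimer: pivot is the smaller species index
  rx <- reaction(c(A = 1, B = 1), NULL, rate = 0.1, specific = TRUE)
  pp <- partialPropensity(rx, c(A = 3, B = 7), 0.1)
  expect_equal(pp$pivot, "A")
  expect_equal(pp$value, 0.7)
  # homodimer at n = 25: a = n * pi
  rx <- reaction(c(A = 2), NULL, rate = 0.032, specific = TRUE)
  pp <- partialPropensity(rx, c(A = 25), 0.032)
  expect_equal(pp$value, 0.032 * 12)
  expect_equal(25 * pp$value, propensity(rx, c(A = 25), 0.032))
})

test_that("a = n_pivot * pi holds across random reactions and states", {
  set.seed(7)
  for (rep in 1:200) {
    type <- sample(c("uni", "hetero", "homo", "a2b", "a3b", "tri"), 1)
    reac <- switch(type,
      uni = c(A = 1), hetero = c(A = 1, B = 1), homo = c(A = 2),
      a2b = c(A = 1, B = 2), a3b = c(A = 1, B = 3), tri = c(A = 3))
    cval <- runif(1, 0.01, 5)
    rx <- reaction(reac, NULL, rate = cval, specific = TRUE)
    counts <- c(A = sample(0:20, 1), B = sample(0:20, 1))
    pp <- partialPropensity(rx, counts, cval)
    a <- propensity(rx, counts, cval)
    expect_equal(counts[[pp$pivot]] * pp$value, a, tolerance = 1e-12)
  }
})

test_that("dependency graph matches brute-force enumeration with self-edges", {
  # cyclic chain: every node has out-degree exactly 2 (self + successor)
  for (N in c(3L, 10L, 100L)) {
    g <- buildDependencyGraph(makeCyclicChain(N))
    expect_true(all(igraph::degree(g, mode = "out") == 2))
    expect_equal(maxOutDegree(g), 2L)
  }
  # isolated conversion reaction: self-edge only
  net <- reactionNetwork(data.frame(id = c("A", "B"), amount = c(1, 0)),
                         list(reaction(c(A = 1), c(B = 1), rate = 1,
                                       specific = TRUE)))
  expect_equal(maxOutDegree(buildDependencyGraph(net)), 1L)
  # empty graph
  empty <- reactionNetwork(data.frame(id = "A", amount = 1), list())
  expect_equal(maxOutDegree(buildDependencyGraph(empty)), 0L)
  # random networks agree with the independent enumeration
  for (seed in 1:5) {
    net <- randomNetwork(S = 6L, M = 10L, seed = seed)
    g <- buildDependencyGraph(net)
    ord <- as.integer(igraph::V(g)$name)
    expect_equal(unname(igraph::degree(g, mode = "out"))[order(ord)],
                 unname(bruteForceOutDegrees(net)))
  }
})

test_that("colloidal aggregation coupling grows as the printed 3N - 7 law", {
  for (N in 4:12) {
    net <- makeColloidalAggregation(N)
    oracle <- max(bruteForceOutDegrees(net))
    expect_equal(maxOutDegree(buildDependencyGraph(net)), oracle)
    if (N >= 5) expect_equal(oracle, 3L * N - 7L)
  }
})
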
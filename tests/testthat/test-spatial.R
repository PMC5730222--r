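test_that("diffusion propensity is n * D/h^2 per neighbor direction", {
  expect_equal(diffusionPropensity(0, 1, 1, 2), 0)
  expect_equal(diffusionPropensity(3, 2, 1, 2), 12)
  expect_equal(diffusionPropensity(1, 1e-12, 1e-6, 1), 1)
  expect_error(diffusionPropensity(1, 1, 0, 1), "positive")
})

test_that("grid geometry matches the boundary condition", {
  net <- reactionNetwork(data.frame(id = "X", amount = 5, diffusion = 1),
                         list(), volume = 1)
  g <- buildGrid(net, dims = 5, h = 1)
  expect_equal(sort(g@neighbors[[1]]), 2L)          # boundary cell: 1 direction
  expect_equal(sort(g@neighbors[[3]]), c(2L, 4L))   # interior: 2 directions
  gp <- buildGrid(net, dims = 5, h = 1, boundary = "periodic")
  expect_equal(sort(gp@neighbors[[1]]), c(2L, 5L))
  g2 <- buildGrid(net, dims = c(3, 3), h = 1)
  expect_equal(length(g2@neighbors[[5]]), 4L)       # 2-D interior
  expect_equal(length(g2@neighbors[[1]]), 2L)       # 2-D corner
})

test_that("uniform initial split conserves the total and warns on immobile species", {
  net <- makeEndosomeSwitch()
  expect_warning(g <- buildGrid(net, dims = 20, h = 1e-7),
                 "immobile.*S0")
  expect_equal(unname(colSums(g@counts)), unname(initialCounts(net)))
  expect_equal(unname(colSums(g@counts)[1]), 2409)
  # remainder goes to low-index subvolumes
  expect_true(all(diff(g@counts[, "R5"]) <= 0))
  # bimolecular/trimolecular rates rescale by nsub^(o-1)
  cs <- networkSpecificRates(net)
  csSub <- networkSpecificRates(g@network)
  expect_equal(csSub[1], cs[1])           # order 1 unchanged
  expect_equal(csSub[2], cs[2] * 20^2)    # order 3
})

test_that("a single diffusing molecule occupies the grid uniformly", {
  net <- reactionNetwork(data.frame(id = "X", amount = 1, diffusion = 50),
                         list(), volume = 1)
  g <- buildGrid(net, dims = 20, h = 1)
  res <- simulateSpatial(g, tEnd = 10000, dt = 5, seed = 6)
  occ <- colSums(res$counts[-(1:200), , 1])   # burn-in discarded
  expect_gt(suppressWarnings(stats::chisq.test(occ)$p.value), 0.01)
  # reflective boundary: the molecule is always somewhere on the grid
  expect_true(all(rowSums(res$counts[, , 1]) == 1L))
})

test_that("diffusion-only species conserve their totals exactly", {
  net <- reactionNetwork(data.frame(id = c("X", "Y"), amount = c(37, 11),
                                    diffusion = c(3, 0.3)), list(), volume = 1)
  g <- buildGrid(net, dims = c(4, 4), h = 1)
  res <- simulateSpatial(g, tEnd = 50, dt = 1, seed = 7)
  expect_true(all(apply(res$counts[, , "X"], 1, sum) == 37L))
  expect_true(all(apply(res$counts[, , "Y"], 1, sum) == 11L))
  expect_gt(res$events, 0)
})

test_that("a 1-subvolume grid reproduces the well-mixed engine distribution", {
  net <- makeHeteroreaction()
  net@diffusion <- c(1, 1)  # mobility is irrelevant on a single subvolume
  g <- buildGrid(net, dims = 1, h = 1)
  aSpatial <- vapply(1:1500, function(i) {
    res <- simulateSpatial(g, tEnd = 50, dt = 50, seed = 40, trajIndex = i)
    res$counts[2, 1, "A"]
  }, integer(1))
  fs <- finalStates(net, "pdm", tEnd = 50, nSamples = 1500, seed = 41)
  expect_gt(chisqSamples(aSpatial, speciesCounts(fs, "A")), 0.01)
  # B stays 1 in the spatial engine too
  res <- simulateSpatial(g, tEnd = 50, dt = 1, seed = 42)
  expect_true(all(res$counts[, , "B"] == 1L))
})

test_that("birth-death totals are Poisson regardless of diffusion", {
  # per-subvolume birth rates sum to the well-mixed rate; internal jumps
  # cannot change the total, which stays Poisson(birth/death)
  net <- reactionNetwork(data.frame(id = "A", amount = 0, diffusion = 2),
                         list(reaction(NULL, c(A = 1), rate = 12, specific = TRUE),
                              reaction(c(A = 1), NULL, rate = 1, specific = TRUE)),
                         volume = 1)
  g <- buildGrid(net, dims = 4, h = 1)
  totals <- vapply(1:1200, function(i) {
    res <- simulateSpatial(g, tEnd = 12, dt = 12, seed = 50, trajIndex = i)
    sum(res$counts[2, , "A"])
  }, integer(1))
  expect_lt(abs(mean(totals) - 12), 3 * sqrt(12 / 1200))
  expect_gt(var(totals) / mean(totals), 0.9)
  expect_lt(var(totals) / mean(totals), 1.1)
})

test_that("fast diffusion drives the 2-cell split toward the binomial limit", {
  # the dimerizing network has a sub-Poissonian stationary marginal, so a
  # slowly coupled pair deviates measurably from the binomial split of the
  # total (a pure birth-death model would satisfy it at any coupling)
  kl2cell <- function(d, seed) {
    net <- reactionNetwork(data.frame(id = "A", amount = 0, diffusion = d),
                           list(reaction(c(A = 2), NULL, rate = 1, specific = TRUE),
                                reaction(NULL, c(A = 1), rate = 40, specific = TRUE)),
                           volume = 1)
    g <- buildGrid(net, dims = 2, h = 1)
    states <- t(vapply(1:2000, function(i) {
      res <- simulateSpatial(g, tEnd = 15, dt = 15, seed = seed, trajIndex = i)
      c(res$counts[2, 1, "A"], res$counts[2, 2, "A"])
    }, integer(2)))
    n1 <- states[, 1]; ntot <- rowSums(states)
    ref <- rowMeans(vapply(ntot, function(nt) stats::dbinom(0:max(ntot), nt, 0.5),
                           numeric(max(ntot) + 1L)))
    emp <- empiricalPdf(n1)
    klDivergence(emp, new("DiscretePDF", support = 0:max(ntot),
                          prob = ref / sum(ref)))
  }
  kls <- c(kl2cell(0.02, 61), kl2cell(0.5, 62), kl2cell(10, 63))
  expect_true(all(diff(kls) < 0))
  expect_lt(kls[3], 0.005)
})

test_that("spatial runs are reproducible from their seeds", {
  net <- reactionNetwork(data.frame(id = "X", amount = 10, diffusion = 1),
                         list(reaction(c(X = 1), NULL, rate = 0.1,
                                       specific = TRUE)), volume = 1)
  g <- buildGrid(net, dims = 5, h = 1)
  r1 <- simulateSpatial(g, tEnd = 20, dt = 1, seed = 77)
  r2 <- simulateSpatial(g, tEnd = 20, dt = 1, seed = 77)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$events, r2$events)
  km <- kymograph(r1, "X")
  expect_equal(dim(km), c(21L, 5L))
  expect_error(kymograph(r1, "Z"), "unknown species")
})
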
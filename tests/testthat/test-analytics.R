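test_that("Bessel-form homoreaction distribution matches the master-equation oracle", {
  pdf <- analyticPdfHomoreaction(312.5)
  expect_true(all(pdf@prob >= 0))
  expect_equal(sum(pdf@prob), 1, tolerance = 1e-12)
  # stationarity of the first factorial moment: 2 (k1/V) E[n(n-1)] = k2 V
  expect_equal(sum(pdf@support * (pdf@support - 1) * pdf@prob), 312.5,
               tolerance = 1e-6)
  cme <- marginalPdf(cmeSteadyState(makeHomoreaction()), "A")
  L <- min(length(cme@prob), length(pdf@prob))
  expect_lt(max(abs(cme@prob[seq_len(L)] - pdf@prob[seq_len(L)])), 1e-8)
  expect_error(analyticPdfHomoreaction(-1), "positive")
})

test_that("heteroreaction distribution is the Poisson of the birth-death balance", {
  pdf <- analyticPdfHeteroreaction(25, nb = 1)
  expect_equal(sum(pdf@support * pdf@prob), 25, tolerance = 1e-12)
  expect_equal(pdf@prob[1], exp(-25), tolerance = 1e-12)
  cme <- marginalPdf(cmeSteadyState(makeHeteroreaction()), "A")
  L <- min(length(cme@prob), length(pdf@prob))
  expect_lt(max(abs(cme@prob[seq_len(L)] - pdf@prob[seq_len(L)])), 1e-10)
  expect_error(analyticPdfHeteroreaction(25, nb = 0), "stationary")
})

test_that("the truncated master-equation solver nails simple birth-death", {
  net <- reactionNetwork(data.frame(id = "A", amount = 0),
                         list(reaction(NULL, c(A = 1), rate = 3, specific = TRUE),
                              reaction(c(A = 1), NULL, rate = 1, specific = TRUE)))
  m <- marginalPdf(cmeSteadyState(net), "A")
  ref <- stats::dpois(m@support, 3)
  expect_lt(max(abs(m@prob - ref / sum(ref))), 1e-10)
})

test_that("pure birth has no stationary distribution and hits the cap", {
  net <- reactionNetwork(data.frame(id = "A", amount = 0),
                         list(reaction(NULL, c(A = 1), rate = 1,
                                       specific = TRUE)))
  expect_error(cmeSteadyState(net, maxStates = 2000), "cap")
})

test_that("empirical distributions are exact relative frequencies", {
  p <- empiricalPdf(c(5L, 5L, 6L))
  expect_equal(p@prob[6:7], c(2 / 3, 1 / 3))
  expect_equal(sum(p@prob), 1)
  deg <- empiricalPdf(rep(3L, 10))
  expect_equal(deg@prob[4], 1)
  expect_error(empiricalPdf(integer(0)), "empty")
  # plug-in KL bias ~ support/(2S): tiny at 1e5 Poisson draws
  set.seed(1)
  kl <- klDivergence(empiricalPdf(stats::rpois(1e5, 25)),
                     analyticPdfHeteroreaction(25, 1))
  expect_lt(kl, 1e-2)
})

test_that("KL divergence behaves like a divergence", {
  p <- new("DiscretePDF", support = 0:1, prob = c(0.5, 0.5))
  expect_equal(klDivergence(p, p), 0)
  q <- new("DiscretePDF", support = 0:1, prob = c(0.25, 0.75))
  expect_equal(klDivergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(klDivergence(p, q), 0.14384, tolerance = 1e-4)
  set.seed(4)
  for (i in 1:100) {
    a <- stats::runif(6); b <- stats::runif(6)
    pa <- new("DiscretePDF", support = 0:5, prob = a / sum(a))
    pb <- new("DiscretePDF", support = 0:5, prob = b / sum(b))
    expect_gte(klDivergence(pa, pb), 0)
  }
  qShort <- new("DiscretePDF", support = 0:0, prob = 1)
  expect_error(klDivergence(p, qShort), "truncation")
})

test_that("convergence-order fits recover known slopes", {
  sizes <- c(100L, 1000L, 10000L)
  exact <- matrix(rep(7 / sizes, each = 3), nrow = 3, byrow = FALSE)
  fit <- convergenceOrder(sizes, exact)
  expect_equal(unname(fit["slope"]), -1, tolerance = 1e-10)
  set.seed(12)
  noisy <- t(replicate(10, (5 / sizes) * (1 + stats::runif(3, -0.2, 0.2))))
  fit <- convergenceOrder(sizes, noisy)
  expect_equal(unname(fit["slope"]), -1, tolerance = 0.1)
  expect_true(fit["stderr"] > 0)
  expect_error(convergenceOrder(c(10, 100), exact[, 1:2]), "3 sample sizes")
  withBad <- exact; withBad[1, 1] <- 0
  expect_warning(convergenceOrder(sizes, withBad), "non-positive")
})

test_that("the scan classifies the no-effector limit as fully switched off", {
  # with S01 = 0 the only R5 source channel is dead forever: R5 decays to 0
  scan <- bifurcationScan(S01Values = 0, nSamples = 10, tEnd = 100, seed = 3)
  expect_true(all(scan$R5 == 0L))
  expect_true(all(scan$switched))
  frac <- switchedFraction(scan)
  expect_equal(frac$fractionSwitched, 1)
})
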
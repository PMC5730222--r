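#' Analytic stationary distribution of the homoreaction model
#'
#' Closed-form steady state of `A + A -> 0`, `0 -> A` under the propensity
#' convention `a_dimer = (k1/V) n (n - 1)`, `a_source = k2 V`:
#' `phi(n)` proportional to `sqrt(2K)^n / n! * I_{n-1}(2 sqrt(2K))` with
#' `K = (k2 V) / (2 k1/V)` and `I` the modified Bessel function of the
#' first kind (the `n = 0` term uses `I_{-1} = I_1`). The result is
#' renormalized numerically over `0..nMax` with `nMax` grown until the
#' appended tail mass is below `1e-12`, which makes the typeset
#' normalization constant moot; the truncated master-equation solver
#' ([cmeSteadyState()]) is the authority this form is verified against.
#'
#' @param K Dimensionless constant `(k2 V) / (2 k1/V)` (> 0).
#' @param nMax Optional support cap; grown automatically when `NULL`.
#' @return A [DiscretePDF-class].
#' @examples
#' pdf <- analyticPdfHomoreaction(312.5)
#' sum(pdf@support * (pdf@support - 1) * pdf@prob)  # = K
#' @export
analyticPdfHomoreaction <- function(K, nMax = NULL) {
  if (K <= 0) stop("K must be positive")
  x <- 2 * sqrt(2 * K)
  logTerm <- function(n) {
    nu <- abs(n - 1)  # I_{-1} = I_1
    n * log(sqrt(2 * K)) - lfactorial(n) +
      log(besselI(x, nu, expon.scaled = TRUE)) + x
  }
  grow <- is.null(nMax)
  if (grow) nMax <- max(50L, ceiling(sqrt(2 * K) + 12 * (2 * K)^0.25))
  repeat {
    lt <- logTerm(0:nMax)
    lt <- lt - max(lt)
    p <- exp(lt)
    if (!grow || p[nMax + 1L] / sum(p) < 1e-15) break
    nMax <- nMax * 2L
  }
  new("DiscretePDF", support = 0:nMax, prob = p / sum(p))
}

#' Analytic stationary distribution of the heteroreaction model
#'
#' Poisson steady state of `A + B -> B`, `0 -> A` at constant `n_b`:
#' `phi(n_a) = (K/n_b)^{n_a} / n_a! * exp(-K/n_b)` with
#' `K = (k2 V) / (k1/V)`, truncated and renormalized on `0..nMax`.
#'
#' @param K Dimensionless constant `(k2 V) / (k1/V)` (> 0).
#' @param nb Constant copy number of B (>= 1; with no B the degradation
#'   channel is dead and A has no stationary distribution).
#' @param nMax Optional support cap; automatic when `NULL`.
#' @return A [DiscretePDF-class].
#' @export
analyticPdfHeteroreaction <- function(K, nb = 1, nMax = NULL) {
  if (K <= 0) stop("K must be positive")
  if (nb < 1) stop("nb must be >= 1: with no B molecules A has no stationary distribution")
  lambda <- K / nb
  if (is.null(nMax))
    nMax <- max(50L, ceiling(lambda + 12 * sqrt(lambda) + 12))
  lp <- stats::dpois(0:nMax, lambda, log = TRUE)
  p <- exp(lp - max(lp))
  new("DiscretePDF", support = 0:nMax, prob = p / sum(p))
}

#' Brute-force stationary distribution of the truncated master equation
#'
#' Independent oracle for stationary distributions: enumerates the states
#' reachable from the initial counts inside a per-species truncation box,
#' assembles the sparse master-equation generator (transitions leaving the
#' box are dropped), and solves for the normalized null vector. The
#' truncation is doubled until the probability mass on boundary states
#' falls below `tol`, or the state cap is exceeded (which is the expected
#' outcome for systems without a stationary distribution, e.g. pure
#' birth).
#'
#' @param net A [ReactionNetwork-class].
#' @param bounds Per-species truncation bounds (scalar recycled); grown
#'   automatically from a heuristic start when `NULL`.
#' @param init Initial counts for the reachability closure.
#' @param maxStates State-space cap (default 1e6).
#' @param tol Acceptable boundary mass (default 1e-10).
#' @return A [CMEStationary-class].
#' @examples
#' cme <- cmeSteadyState(makeHeteroreaction())
#' marginalPdf(cme, "A")
#' @export
cmeSteadyState <- function(net, bounds = NULL, init = initialCounts(net),
                           maxStates = 1e6, tol = 1e-10) {
  rep <- validateNetwork(net)
  if (length(rep)) stop("invalid network: ", paste(rep, collapse = "; "))
  ids <- net@species
  S <- length(ids)
  cs <- networkSpecificRates(net)
  deltas <- lapply(net@reactions, function(rx) {
    d <- reactionDelta(rx)
    full <- setNames(integer(S), ids)
    full[names(d)] <- d
    unname(full)
  })
  init <- as.integer(init[ids])
  if (is.null(bounds)) bounds <- pmax(init * 2L + 20L, 40L)
  bounds <- as.integer(rep(bounds, length.out = S))

  repeat {
    if (prod(bounds + 1) > maxStates * 8)  # cheap pre-check before BFS
      stop("state-space truncation exceeds the cap (", maxStates,
           " states); the system may have no stationary distribution ",
           "or needs a smaller model")
    sol <- .cmeSolve(deltas, net, cs, init, bounds, maxStates)
    if (sol$boundaryMass < tol)
      return(new("CMEStationary", states = sol$states, prob = sol$prob,
                 species = ids, boundaryMass = sol$boundaryMass))
    bounds <- bounds * 2L
  }
}

.cmeSolve <- function(deltas, net, cs, init, bounds, maxStates) {
  S <- length(init)
  key <- function(x) paste(x, collapse = ",")
  stateIndex <- new.env(hash = TRUE, parent = emptyenv())
  states <- list(init)
  assign(key(init), 1L, envir = stateIndex)
  # BFS reachability closure inside the box
  head <- 1L
  while (head <= length(states)) {
    x <- states[[head]]
    for (d in deltas) {
      y <- x + d
      if (any(y < 0L) || any(y > bounds)) next
      k <- key(y)
      if (is.null(stateIndex[[k]])) {
        states[[length(states) + 1L]] <- y
        assign(k, length(states), envir = stateIndex)
        if (length(states) > maxStates)
          stop("state-space truncation exceeds the cap (", maxStates,
               " states); the system may have no stationary distribution ",
               "or needs a smaller model")
      }
    }
    head <- head + 1L
  }
  N <- length(states)
  stmat <- do.call(rbind, states)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_ <- numeric(N)
  for (m in seq_along(deltas)) {
    rx <- net@reactions[[m]]
    rs <- rx@reactants
    rIdx <- match(names(rs), net@species)
    a <- rep(cs[m], N)
    for (t in seq_along(rIdx)) a <- a * choose(stmat[, rIdx[t]], rs[[t]])
    tgt <- sweep(stmat, 2, deltas[[m]], "+")
    ok <- a > 0 & !apply(tgt < 0L | sweep(tgt, 2, bounds, ">"), 1, any)
    if (!any(ok)) next
    tgtKeys <- apply(tgt[ok, , drop = FALSE], 1, key)
    jIdx <- vapply(tgtKeys, function(k) stateIndex[[k]], integer(1))
    src <- which(ok)
    ii <- c(ii, jIdx); jj <- c(jj, src); vv <- c(vv, a[ok])
    diag_[src] <- diag_[src] + a[ok]
  }
  # generator transpose A with A[i,j] = rate(j -> i), diagonal -outflow;
  # stationary p solves A p = 0, replace one balance row by normalization
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(vv, -diag_), dims = c(N, N))
  A[N, ] <- 1
  b <- c(rep(0, N - 1L), 1)
  p <- as.numeric(Matrix::solve(A, b))
  p[p < 0 & p > -1e-12] <- 0
  p <- p / sum(p)
  # boundary mass: states sitting on the truncation bound of any species
  # that the dynamics can actually change (a conserved species never
  # reaches its bound and must not flag the truncation as inadequate)
  changeable <- which(vapply(seq_len(S), function(s)
    any(vapply(deltas, function(d) d[s] != 0L, logical(1))), logical(1)))
  bm <- if (length(changeable)) {
    onB <- rep(FALSE, N)
    for (s in changeable) onB <- onB | (stmat[, s] == bounds[s])
    sum(p[onB])
  } else 0
  list(states = stmat, prob = p, boundaryMass = bm)
}

#' Marginal distribution of one species from a joint stationary solution
#'
#' @param cme A [CMEStationary-class].
#' @param species Species identifier.
#' @return A [DiscretePDF-class] on `0..max` observed for that species.
#' @export
marginalPdf <- function(cme, species) {
  s <- match(species, cme@species)
  if (is.na(s)) stop("unknown species '", species, "'")
  vals <- cme@states[, s]
  nMax <- max(vals)
  p <- vapply(0:nMax, function(v) sum(cme@prob[vals == v]), numeric(1))
  p[p < 0] <- 0
  new("DiscretePDF", support = 0:nMax, prob = p / sum(p))
}

#' Empirical distribution of Monte-Carlo samples
#'
#' Relative frequencies of one species over `0..max(observed)`.
#'
#' @param x A [SampleSet-class], or an integer vector of samples.
#' @param species Species identifier (required for a sample set).
#' @return A [DiscretePDF-class].
#' @export
empiricalPdf <- function(x, species = NULL) {
  v <- if (is(x, "SampleSet")) speciesCounts(x, species) else as.integer(x)
  if (length(v) == 0L) stop("empty sample set")
  nMax <- max(v)
  p <- tabulate(v + 1L, nbins = nMax + 1L) / length(v)
  new("DiscretePDF", support = 0:nMax, prob = p)
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' `sum over p(n) > 0 of p(n) log(p(n)/q(n))`, with `q` evaluated as 0
#' outside its support. An error is raised when `q` is zero somewhere `p`
#' has mass (signals an inadequate reference truncation).
#'
#' @param p,q [DiscretePDF-class] objects (`p` = empirical/simulated,
#'   `q` = reference).
#' @return Non-negative divergence; 0 iff the distributions agree on the
#'   support of `p`.
#' @examples
#' p <- new("DiscretePDF", support = 0:1, prob = c(0.5, 0.5))
#' q <- new("DiscretePDF", support = 0:1, prob = c(0.25, 0.75))
#' klDivergence(p, q)  # 0.5*log(2) + 0.5*log(2/3)
#' @export
klDivergence <- function(p, q) {
  qAt <- function(n) {
    i <- match(n, q@support)
    ifelse(is.na(i), 0, q@prob[i])
  }
  on <- p@prob > 0
  qv <- qAt(p@support[on])
  if (any(qv == 0))
    stop("reference distribution has zero mass on the simulated support ",
         "(inadequate reference truncation)")
  sum(p@prob[on] * log(p@prob[on] / qv))
}

#' Weak order of convergence from a KL-vs-samples study
#'
#' Least-squares slope of mean `log(KL)` against `log(S)` over the sample
#' sizes, with the standard error computed across repetitions (one slope
#' per repetition). Non-positive KL values are excluded with a warning.
#'
#' @param sampleSizes Integer vector of Monte-Carlo sample counts (>= 3).
#' @param klValues Matrix of KL divergences, repetitions x sizes.
#' @return Named vector `c(slope, stderr)`.
#' @export
convergenceOrder <- function(sampleSizes, klValues) {
  if (length(sampleSizes) < 3L) stop("need at least 3 sample sizes")
  if (is.null(dim(klValues))) klValues <- matrix(klValues, nrow = 1)
  if (nrow(klValues) < 2L) stop("need at least 2 repetitions")
  if (any(klValues <= 0)) {
    warning("excluding non-positive KL values from the fit")
    klValues[klValues <= 0] <- NA
  }
  lS <- log(sampleSizes)
  meanLog <- colMeans(log(klValues), na.rm = TRUE)
  slope <- unname(stats::coef(stats::lm(meanLog ~ lS))[2])
  repSlopes <- apply(klValues, 1, function(r) {
    ok <- !is.na(r)
    if (sum(ok) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(log(r[ok]) ~ lS[ok]))[2])
  })
  repSlopes <- repSlopes[!is.na(repSlopes)]
  stderr <- stats::sd(repSlopes) / sqrt(length(repSlopes))
  c(slope = slope, stderr = stderr)
}

#' KL-divergence convergence study for a validation model
#'
#' Full pipeline behind the weak-convergence check: for each sample size
#' `S` and repetition, draw `S` final states at `tEnd`, form the empirical
#' distribution of `species`, and compute its KL divergence against the
#' analytic reference. Streams are disjoint across repetitions and sizes.
#'
#' @param net A [ReactionNetwork-class].
#' @param reference A [DiscretePDF-class] (strictly positive analytic
#'   stationary distribution).
#' @param species Species to track.
#' @param method Engine name.
#' @param sampleSizes Monte-Carlo sample counts.
#' @param reps Repetitions per size.
#' @param tEnd Steady-state sampling time.
#' @param seed Master seed.
#' @return Matrix of KL values, `reps` x `length(sampleSizes)`.
#' @export
klConvergenceStudy <- function(net, reference, species, method = "pdm",
                               sampleSizes = c(100L, 1000L, 10000L),
                               reps = 10L, tEnd = 100, seed = 1L) {
  kl <- matrix(NA_real_, reps, length(sampleSizes))
  offset <- 0
  for (j in seq_along(sampleSizes)) {
    for (r in seq_len(reps)) {
      fs <- finalStates(net, method, tEnd = tEnd,
                        nSamples = sampleSizes[j], seed = seed,
                        streamOffset = offset)
      offset <- offset + sampleSizes[j]
      kl[r, j] <- klDivergence(empiricalPdf(fs, species), reference)
    }
  }
  kl
}

#' Bifurcation scan of the endosome cut-out switch
#'
#' For each total effector concentration `S01`, runs `nSamples`
#' trajectories of the endosome model from the early-endosome initial
#' condition and classifies each final state as *switched* iff the final
#' R5 count falls below `theta` times the initial R5 count.
#'
#' @param S01Values Concentrations to scan (mol m^-3). The default grid
#'   spans the transition of the default parameter set.
#' @param nSamples Trajectories per value (default 100).
#' @param tEnd Simulated minutes per trajectory (default 100).
#' @param seed Master seed.
#' @param theta Switch-classification threshold (fraction of the initial
#'   R5 count, default 0.5).
#' @param method Engine name (default `"pdm"`).
#' @param params Base parameters from [endosomeParams()]; `S01` is
#'   overridden by the scan.
#' @return Data frame with columns `S01`, `sample`, `R5`, `R7`,
#'   `switched`.
#' @export
bifurcationScan <- function(S01Values = defaultScanGrid(), nSamples = 100L,
                            tEnd = 100, seed = 1L, theta = 0.5,
                            method = "pdm", params = endosomeParams()) {
  stopifnot(nSamples >= 1)
  out <- vector("list", length(S01Values))
  for (i in seq_along(S01Values)) {
    params$S01 <- S01Values[i]
    net <- makeEndosomeSwitch(params)
    r5init <- initialCounts(net)[["R5"]]
    fs <- finalStates(net, method, tEnd = tEnd, nSamples = nSamples,
                      seed = seed, streamOffset = (i - 1) * nSamples)
    out[[i]] <- data.frame(
      S01 = S01Values[i], sample = seq_len(nSamples),
      R5 = speciesCounts(fs, "R5"), R7 = speciesCounts(fs, "R7"),
      switched = speciesCounts(fs, "R5") < theta * r5init)
  }
  do.call(rbind, out)
}

#' Default S01 scan grid for the endosome bifurcation scan
#'
#' Linear grid of effector concentrations (mol m^-3) spanning the
#' stochastic transition of the default parameter set. The upper end sits
#' past the deterministic saddle-node of the R7 subsystem near
#' `S01 = k3 / (2 sqrt(k21 k22)) ~ 1.6 mol m^-3`. The lower end stays
#' above ~0.5 mol m^-3 because the switch classification compares final
#' R5 against a fraction `theta` of the *fixed* early-endosome initial
#' count: below that concentration the unswitched R5 steady level
#' (`~ k01 S01 / k1`) itself drops under the threshold and the
#' classification degenerates.
#'
#' @return Numeric vector of concentrations.
#' @export
defaultScanGrid <- function() seq(0.6, 2.0, by = 0.2)

#' Fraction of switched samples per scan value
#'
#' @param scan Data frame from [bifurcationScan()].
#' @return Data frame with columns `S01` and `fractionSwitched`.
#' @export
switchedFraction <- function(scan) {
  agg <- stats::aggregate(switched ~ S01, data = scan, FUN = mean)
  names(agg)[2] <- "fractionSwitched"
  agg[order(agg$S01), ]
}
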
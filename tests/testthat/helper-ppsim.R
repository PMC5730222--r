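# Shared fixtures and statistical helpers.

# Random small mass-action network: species X1..XS, a source channel plus
# random unimolecular / heterodimer / homodimer / A+2B channels. Used for
# property-style checks of the partial-propensity bookkeeping.
randomNetwork <- function(S = 8L, M = 12L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("X%d", seq_len(S))
  rxns <- list(reaction(NULL, setNames(1L, sample(ids, 1)),
                        rate = runif(1, 0.5, 2), specific = TRUE))
  for (m in seq_len(M - 1L)) {
    type <- sample(c("uni", "hetero", "homo", "a2b", "source"), 1)
    prodN <- sample(0:2, 1)
    prods <- if (prodN == 0) NULL else {
      p <- table(sample(ids, prodN, replace = TRUE))
      setNames(as.integer(p), names(p))
    }
    reac <- switch(type,
      source = NULL,
      uni = setNames(1L, sample(ids, 1)),
      homo = setNames(2L, sample(ids, 1)),
      hetero = setNames(c(1L, 1L), sample(ids, 2)),
      a2b = setNames(c(1L, 2L), sample(ids, 2)))
    rxns[[m + 1L]] <- reaction(reac, prods, rate = runif(1, 0.1, 2),
                               specific = TRUE)
  }
  reactionNetwork(data.frame(id = ids, amount = sample(0:30, S, replace = TRUE)),
                  rxns, volume = 1, name = sprintf("random_%d", seed))
}

# Two-sample chi-square on integer samples: adjacent outcome bins merged
# until each pooled bin holds at least `minPool` observations.
chisqSamples <- function(x, y, minPool = 20L) {
  lo <- min(x, y); hi <- max(x, y)
  tx <- tabulate(x - lo + 1L, nbins = hi - lo + 1L)
  ty <- tabulate(y - lo + 1L, nbins = hi - lo + 1L)
  tot <- tx + ty
  gx <- numeric(0); gy <- numeric(0)
  cx <- 0; cy <- 0; ct <- 0
  for (i in seq_along(tot)) {
    cx <- cx + tx[i]; cy <- cy + ty[i]; ct <- ct + tot[i]
    if (ct >= minPool) {
      gx <- c(gx, cx); gy <- c(gy, cy)
      cx <- 0; cy <- 0; ct <- 0
    }
  }
  if (ct > 0 && length(gx)) {
    gx[length(gx)] <- gx[length(gx)] + cx
    gy[length(gy)] <- gy[length(gy)] + cy
  }
  if (length(gx) < 2L) return(1)  # indistinguishable: everything in one bin
  suppressWarnings(stats::chisq.test(rbind(gx, gy))$p.value)
}

# Chi-square of observed channel counts against exact probabilities.
chisqChannels <- function(channels, probs) {
  obs <- tabulate(channels, nbins = length(probs))
  suppressWarnings(stats::chisq.test(obs, p = probs)$p.value)
}

# Independent brute-force dependency-graph oracle: out-degree of every
# reaction, counting nu whenever firing mu changes a reactant of nu
# (self-edges included). Works directly from the reaction slots.
bruteForceOutDegrees <- function(net) {
  rxns <- reactions(net)
  deltaOf <- function(rx) {
    all <- union(names(rx@reactants), names(rx@products))
    d <- setNames(integer(length(all)), all)
    for (s in names(rx@products)) d[s] <- d[s] + rx@products[[s]]
    for (s in names(rx@reactants)) d[s] <- d[s] - rx@reactants[[s]]
    names(d)[d != 0L]
  }
  changed <- lapply(rxns, deltaOf)
  reacts <- lapply(rxns, function(rx) names(rx@reactants))
  vapply(seq_along(rxns), function(mu)
    sum(vapply(seq_along(rxns), function(nu)
      length(intersect(changed[[mu]], reacts[[nu]])) > 0L, logical(1))),
    integer(1))
}
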
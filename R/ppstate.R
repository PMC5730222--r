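#' Build the partial-propensity structure for a network state
#'
#' Factorizes every channel propensity as `a = n_pivot * pi` (see
#' [partialPropensity()]) and lays the `pi` values out in rows: row 1 holds
#' source (zeroth-order) channels, row `i + 1` the channels pivoted on
#' species `i`. Row sums `Lambda`, group sums `Sigma = n * Lambda`
#' (`Sigma[1] = Lambda[1]`) and the total propensity `a0 = sum(Sigma)`
#' drive the two-level "which molecule / which partner" sampling of the
#' partial-propensity methods. This R implementation is the reference used
#' to verify the compiled engines' incremental bookkeeping.
#'
#' @param net A [ReactionNetwork-class].
#' @param counts Named integer state; defaults to the initial state.
#' @return A [PartialPropensityState-class].
#' @examples
#' pps <- buildPPState(makeHomoreaction())
#' pps@a0  # 0.016 * 25 * 24 + 10
#' @export
buildPPState <- function(net, counts = initialCounts(net)) {
  ids <- net@species
  S <- length(ids)
  counts <- as.integer(counts[ids])
  cs <- networkSpecificRates(net)
  rows <- rep(list(numeric(0)), S + 1L)
  rowRxns <- rep(list(integer(0)), S + 1L)
  dependents <- rep(list(integer(0)), S)
  names(dependents) <- ids
  namedCounts <- setNames(counts, ids)
  for (m in seq_along(net@reactions)) {
    rx <- net@reactions[[m]]
    pp <- partialPropensity(rx, namedCounts, cs[m], speciesOrder = ids)
    r <- if (pp$pivot == "source") 1L else match(pp$pivot, ids) + 1L
    rows[[r]] <- c(rows[[r]], pp$value)
    rowRxns[[r]] <- c(rowRxns[[r]], m)
    # entries depending on a species count: the non-pivot reactant, or the
    # pivot itself when its stoichiometry exceeds one
    rs <- rx@reactants
    if (length(rs) == 2L) {
      other <- setdiff(names(rs), pp$pivot)
      dependents[[other]] <- c(dependents[[other]], m)
    } else if (length(rs) == 1L && rs[[1]] > 1L) {
      dependents[[names(rs)]] <- c(dependents[[names(rs)]], m)
    }
  }
  Lambda <- vapply(rows, sum, numeric(1))
  Sigma <- Lambda
  if (S > 0) Sigma[-1L] <- counts * Lambda[-1L]
  new("PartialPropensityState",
      rows = rows, rowRxns = rowRxns, Lambda = Lambda, Sigma = Sigma,
      a0 = sum(Sigma), counts = counts, dependents = dependents)
}

#' Incrementally update a partial-propensity structure after one firing
#'
#' Applies the net stoichiometric change of `reactionIndex` to the counts
#' and recomputes exactly the entries listed in the update tables for the
#' changed species, adjusting `Lambda`, `Sigma` and `a0` incrementally.
#' A full rebuild via [buildPPState()] must reproduce the result entrywise;
#' that property is the correctness oracle for this bookkeeping.
#'
#' @param pps A [PartialPropensityState-class].
#' @param net The network the structure was built for.
#' @param reactionIndex Index of the fired channel (its propensity must be
#'   positive in the current state).
#' @return The updated [PartialPropensityState-class].
#' @export
ppApplyUpdate <- function(pps, net, reactionIndex) {
  ids <- net@species
  rx <- net@reactions[[reactionIndex]]
  counts <- setNames(pps@counts, ids)
  cs <- networkSpecificRates(net)
  if (propensity(rx, counts, cs[reactionIndex]) <= 0)
    stop("reaction ", reactionIndex, " is not fireable in this state")
  delta <- reactionDelta(rx)
  newCounts <- counts
  newCounts[names(delta)] <- newCounts[names(delta)] + delta
  if (any(newCounts < 0))
    stop("internal error: firing reaction ", reactionIndex,
         " would drive a count negative")
  touched <- integer(0)
  for (sp in names(delta)) {
    for (m in pps@dependents[[sp]]) {
      ppv <- partialPropensity(net@reactions[[m]], newCounts, cs[m],
                               speciesOrder = ids)
      r <- if (ppv$pivot == "source") 1L else match(ppv$pivot, ids) + 1L
      col <- match(m, pps@rowRxns[[r]])
      old <- pps@rows[[r]][col]
      pps@rows[[r]][col] <- ppv$value
      pps@Lambda[r] <- pps@Lambda[r] + (ppv$value - old)
      touched <- union(touched, r)
    }
    touched <- union(touched, match(sp, ids) + 1L)
  }
  pps@counts <- as.integer(newCounts)
  for (r in touched) {
    newSigma <- if (r == 1L) pps@Lambda[1L]
                else newCounts[[r - 1L]] * pps@Lambda[r]
    pps@a0 <- pps@a0 + (newSigma - pps@Sigma[r])
    pps@Sigma[r] <- newSigma
  }
  pps
}

setMethod("show", "PartialPropensityState", function(object) {
  cat("PartialPropensityState: ", length(object@counts), " species, a0 = ",
      format(object@a0), "\n", sep = "")
  cat("  Sigma:", paste(format(object@Sigma, digits = 4), collapse = " "), "\n")
})
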
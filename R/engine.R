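#' @useDynLib ppsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.METHODS <- c("dm", "pdm", "spdm", "pssacr", "dpdm", "psrd")

.checkMethod <- function(method, spatial = FALSE) {
  method <- tolower(method)
  valid <- if (spatial) .METHODS else setdiff(.METHODS, "psrd")
  if (!method %in% valid)
    stop("unknown method '", method, "'; valid methods: ",
         paste(.METHODS, collapse = ", "),
         if (!spatial) " (psrd requires a SubvolumeGrid)")
  method
}

# Flatten a ReactionNetwork into the list the compiled engines consume
# (0-based species indices, specific rates resolved).
.engineModel <- function(net) {
  rep <- validateNetwork(net)
  if (length(rep)) stop("invalid network: ", paste(rep, collapse = "; "))
  ids <- net@species
  cs <- networkSpecificRates(net)
  idx <- function(v) as.integer(match(names(v), ids) - 1L)
  list(
    nSpecies = length(ids),
    reactantIdx = lapply(net@reactions, function(r) idx(r@reactants)),
    reactantSt = lapply(net@reactions, function(r) as.integer(unname(r@reactants))),
    productIdx = lapply(net@reactions, function(r) idx(r@products)),
    productSt = lapply(net@reactions, function(r) as.integer(unname(r@products))),
    c = as.numeric(cs),
    delay = vapply(net@reactions, function(r) r@delay, numeric(1)),
    consuming = vapply(net@reactions, function(r) r@delayConsuming, logical(1))
  )
}

#' Run one exact SSA trajectory
#'
#' Simulates the network with the chosen engine and records the state on
#' the uniform grid `t_k = k * dt` up to `tEnd` (the recorded state at
#' `t_k` is the state after all events with time `<= t_k`). Identical
#' `(net, method, seed, trajIndex)` give bit-identical records. The loop
#' ends at `tEnd`, or earlier when the total propensity reaches zero with
#' an empty delay queue (remaining grid points repeat the frozen state).
#'
#' @param net A [ReactionNetwork-class].
#' @param method One of `"dm"`, `"pdm"`, `"spdm"`, `"pssacr"`, `"dpdm"`.
#' @param tEnd End time (> 0).
#' @param dt Recording interval (> 0).
#' @param seed Integer master seed.
#' @param trajIndex Trajectory index; (seed, trajIndex) determines the
#'   random stream, so trajectories are reproducible independently of
#'   execution order.
#' @return A [TrajectoryRecord-class].
#' @examples
#' tr <- ssa(makeHomoreaction(), "pdm", tEnd = 10, dt = 1, seed = 1)
#' @export
ssa <- function(net, method = "pdm", tEnd, dt, seed = 1L, trajIndex = 0L) {
  method <- .checkMethod(method)
  stopifnot(tEnd > 0, dt > 0)
  res <- cpp_simulate(.engineModel(net), net@initialCounts, method,
                      tEnd, dt, as.numeric(seed), as.numeric(trajIndex))
  counts <- res$counts
  colnames(counts) <- net@species
  new("TrajectoryRecord", times = res$times, counts = counts,
      species = net@species, method = method, seed = as.integer(seed),
      events = res$events)
}

#' Run many trajectories and collect final states
#'
#' Monte-Carlo sampling of the state at `tEnd`: each sample runs an
#' independent trajectory on its own random stream derived from
#' `(seed, streamOffset + i)`.
#'
#' @inheritParams ssa
#' @param nSamples Number of trajectories.
#' @param streamOffset Offset added to the per-sample stream index (use to
#'   make successive calls draw disjoint streams).
#' @return A [SampleSet-class].
#' @examples
#' fs <- finalStates(makeHeteroreaction(), "pdm", tEnd = 10, nSamples = 100, seed = 1)
#' @export
finalStates <- function(net, method = "pdm", tEnd, nSamples, seed = 1L,
                        streamOffset = 0) {
  method <- .checkMethod(method)
  stopifnot(tEnd > 0, nSamples >= 1)
  res <- cpp_final_states(.engineModel(net), net@initialCounts, method,
                          tEnd, as.integer(nSamples), as.numeric(seed),
                          as.numeric(streamOffset))
  states <- res$states
  colnames(states) <- net@species
  new("SampleSet", states = states, species = net@species, method = method,
      seed = as.integer(seed), tEnd = tEnd)
}

#' Sample (waiting time, channel) pairs from a frozen state
#'
#' Draws next-event pairs repeatedly from the same population state without
#' applying updates: waiting times are Exp(a0) and the channel is chosen
#' with probability `a_mu / a0` by the selected engine's sampling scheme
#' (SPDM still bubbles its scan order between draws). Used to verify the
#' samplers against exact propensity ratios.
#'
#' @inheritParams ssa
#' @param counts Named state to freeze; defaults to the initial state.
#' @param nDraws Number of draws.
#' @return List with integer vector `channel` (1-based), numeric `wait`,
#'   and the structure's total propensity `a0`.
#' @export
sampleEvents <- function(net, method = "pdm", counts = initialCounts(net),
                         nDraws = 1000L, seed = 1L) {
  method <- .checkMethod(method)
  cpp_sample_events(.engineModel(net), as.integer(counts[net@species]),
                    method, as.integer(nDraws), as.numeric(seed))
}

#' Check incremental total-propensity bookkeeping
#'
#' Runs one trajectory with periodic rebuilds disabled and returns the
#' incrementally maintained `a0` together with the directly recomputed
#' propensity sum at the final state.
#'
#' @inheritParams ssa
#' @return List with `a0` (incremental), `direct` (recomputed) and
#'   `events`.
#' @keywords internal
#' @export
a0Drift <- function(net, method = "pdm", tEnd, seed = 1L) {
  method <- .checkMethod(method)
  cpp_a0_drift(.engineModel(net), net@initialCounts, method, tEnd,
               as.numeric(seed))
}

#' Extract a species column from a trajectory or sample set
#'
#' @param x A [TrajectoryRecord-class] or [SampleSet-class].
#' @param species Species identifier.
#' @return Integer vector of counts.
#' @export
speciesCounts <- function(x, species) {
  m <- if (is(x, "TrajectoryRecord")) x@counts else x@states
  if (!species %in% colnames(m))
    stop("unknown species '", species, "'; available: ",
         paste(colnames(m), collapse = ", "))
  m[, species]
}
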
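#' Wall-clock runtime per simulated event
#'
#' Times one trajectory and divides by the number of events fired.
#' Intended for the non-binding scaling benchmarks (runtime per event as a
#' function of system size for the weakly and strongly coupled benchmark
#' networks); absolute numbers are hardware-dependent.
#'
#' @inheritParams ssa
#' @return Named list with `secondsPerEvent`, `events` and `seconds`.
#' @export
runtimePerEvent <- function(net, method = "pdm", tEnd = 10, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  tr <- ssa(net, method, tEnd = tEnd, dt = tEnd, seed = seed)
  el <- proc.time()[["elapsed"]] - t0
  if (tr@events == 0) stop("no events fired; increase tEnd")
  list(secondsPerEvent = el / tr@events, events = tr@events, seconds = el)
}

#' Runtime-scaling benchmark over system size
#'
#' Runs [runtimePerEvent()] for each combination of model family, size and
#' method.
#'
#' @param family `"cyclic_chain"` or `"colloidal_aggregation"`.
#' @param sizes Integer vector of species counts `N`.
#' @param methods Engine names to compare.
#' @param tEnd Simulated time per run.
#' @param seed Master seed.
#' @return Data frame with columns `family`, `N`, `method`,
#'   `secondsPerEvent`, `events`.
#' @export
benchmarkScaling <- function(family = c("cyclic_chain", "colloidal_aggregation"),
                             sizes = c(10L, 30L, 100L),
                             methods = c("dm", "pdm", "spdm", "pssacr"),
                             tEnd = 10, seed = 1L) {
  family <- match.arg(family)
  make <- if (family == "cyclic_chain") makeCyclicChain
          else makeColloidalAggregation
  out <- expand.grid(family = family, N = sizes, method = methods,
                     stringsAsFactors = FALSE)
  out$secondsPerEvent <- NA_real_
  out$events <- NA_real_
  for (i in seq_len(nrow(out))) {
    net <- make(out$N[i], n0 = 10L)
    r <- runtimePerEvent(net, out$method[i], tEnd = tEnd, seed = seed)
    out$secondsPerEvent[i] <- r$secondsPerEvent
    out$events[i] <- r$events
  }
  out
}
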
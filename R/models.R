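#' Homoreaction validation model
#'
#' Two channels, `A + A -> 0` and `0 -> A`, stated via the lumped constants
#' `k1/V` and `k2*V` which enter directly as specific probability rates.
#' Under the `choose(n, 2)` degeneracy convention the dimerization channel
#' uses `c = 2 * k1/V`, so its propensity is `(k1/V) * n * (n - 1)`; this
#' is the convention under which the Bessel-form stationary distribution
#' (see [analyticPdfHomoreaction()]) agrees with the truncated
#' master-equation solution.
#'
#' @param k1OverV Lumped dimerization constant `k1/V` (default 0.016 s^-1).
#' @param k2TimesV Lumped production constant `k2*V` (default 10 s^-1).
#' @param n0 Initial copy number of A (default 25).
#' @return A [ReactionNetwork-class].
#' @export
makeHomoreaction <- function(k1OverV = 0.016, k2TimesV = 10, n0 = 25) {
  stopifnot(k1OverV > 0, k2TimesV > 0, n0 >= 0)
  reactionNetwork(
    data.frame(id = "A", amount = n0),
    list(reaction(c(A = 2), NULL, rate = 2 * k1OverV, specific = TRUE),
         reaction(NULL, c(A = 1), rate = k2TimesV, specific = TRUE)),
    volume = 1, name = "homoreaction", units = "s")
}

#' Heteroreaction validation model
#'
#' Two channels, `A + B -> B` and `0 -> A`, with lumped constants entering
#' as specific rates. Species B is conserved by both channels, so its copy
#' number never changes; the stationary distribution of A is Poisson (see
#' [analyticPdfHeteroreaction()]).
#'
#' @param k1OverV Lumped constant `k1/V` (default 0.04 s^-1).
#' @param k2TimesV Lumped constant `k2*V` (default 1 s^-1).
#' @param na0 Initial copy number of A (default 25).
#' @param nb0 Initial (and perpetual) copy number of B (default 1).
#' @return A [ReactionNetwork-class].
#' @export
makeHeteroreaction <- function(k1OverV = 0.04, k2TimesV = 1, na0 = 25, nb0 = 1) {
  stopifnot(k1OverV > 0, k2TimesV > 0, na0 >= 0, nb0 >= 0)
  reactionNetwork(
    data.frame(id = c("A", "B"), amount = c(na0, nb0)),
    list(reaction(c(A = 1, B = 1), c(B = 1), rate = k1OverV, specific = TRUE),
         reaction(NULL, c(A = 1), rate = k2TimesV, specific = TRUE)),
    volume = 1, name = "heteroreaction", units = "s")
}

#' Cyclic linear chain benchmark model
#'
#' `N` species and `N` unimolecular conversions `S_i -> S_{i+1}` closed by
#' `S_N -> S_1`: the most weakly coupled network possible, with dependency-
#' graph out-degree exactly 2 at every node (self plus successor). Total
#' population is conserved.
#'
#' @param N Number of species (and reactions), `N >= 2`.
#' @param k Unimolecular rate for every channel (default 1).
#' @param n0 Initial copy number of every species (default 1).
#' @return A [ReactionNetwork-class].
#' @export
makeCyclicChain <- function(N, k = 1, n0 = 1) {
  if (N < 2) stop("cyclic chain requires N >= 2")
  ids <- sprintf("S%d", seq_len(N))
  rxns <- lapply(seq_len(N), function(i) {
    j <- if (i == N) 1L else i + 1L
    reaction(setNames(1L, ids[i]), setNames(1L, ids[j]),
             rate = k, specific = TRUE)
  })
  reactionNetwork(data.frame(id = ids, amount = rep(n0, N)), rxns,
                  volume = 1, name = sprintf("cyclic_chain_N%d", N))
}

#' Colloidal aggregation benchmark model
#'
#' Aggregation channels `S_n + S_m -> S_{n+m}` for `n = 1..floor(N/2)`,
#' `m = n..N-n`, and fragmentation channels `S_p -> S_q + S_{p-q}` for
#' `p = 1..N`, `q = 1..floor(p/2)` — `floor(N^2/2)` reactions in total, a
#' strongly coupled network whose dependency-graph maximum out-degree grows
#' as `3N - 7`. Mass `sum(i * n_i)` is conserved by every channel.
#' Channels are enumerated aggregation-first in `(n, m)` lexicographic
#' order, then fragmentation in `(p, q)` order.
#'
#' @param N Number of species, `N >= 2`.
#' @param k Rate constant for every channel (default 1, specific).
#' @param n0 Initial copy number of every species (default 1).
#' @return A [ReactionNetwork-class].
#' @export
makeColloidalAggregation <- function(N, k = 1, n0 = 1) {
  if (N < 2) stop("colloidal aggregation requires N >= 2")
  ids <- sprintf("S%d", seq_len(N))
  rxns <- list()
  for (n in seq_len(N %/% 2L)) {
    for (m in n:(N - n)) {
      lhs <- if (n == m) setNames(2L, ids[n]) else setNames(c(1L, 1L), ids[c(n, m)])
      rxns[[length(rxns) + 1L]] <-
        reaction(lhs, setNames(1L, ids[n + m]), rate = k, specific = TRUE)
    }
  }
  for (p in seq_len(N)) {
    if (p < 2L) next
    for (q in seq_len(p %/% 2L)) {
      rhs <- if (q == p - q) setNames(2L, ids[q]) else setNames(c(1L, 1L), ids[c(q, p - q)])
      rxns[[length(rxns) + 1L]] <-
        reaction(setNames(1L, ids[p]), rhs, rate = k, specific = TRUE)
    }
  }
  reactionNetwork(data.frame(id = ids, amount = rep(n0, N)), rxns,
                  volume = 1, name = sprintf("colloidal_aggregation_N%d", N))
}

#' Parameters of the endosome cut-out-switch model
#'
#' Defaults are the published operating point of the Rab5/Rab7 conversion
#' network: rates in minutes and SI concentration units, compartment volume
#' `4e-21` m^3, early-endosome initial condition (`R5 = 1 mol m^-3`,
#' `R7 = 0`, `S0 = S01`, `S1 = 0`).
#'
#' @param S01 Total effector concentration `S0 + S1` (mol m^-3).
#' @param k01,k02,k0m2,k1,k21,k22,k3 Rate constants (min^-1 for first-order
#'   channels, m^6 mol^-2 min^-1 for the trimolecular ones).
#' @param R5Init,R7Init Initial Rab concentrations (mol m^-3).
#' @param V Compartment volume (m^3).
#' @return Named list of parameters for [makeEndosomeSwitch()].
#' @export
endosomeParams <- function(S01 = 1.0, k01 = 1, k02 = 100, k0m2 = 10,
                           k1 = 1, k21 = 0.1, k22 = 100, k3 = 10,
                           R5Init = 1.0, R7Init = 0, V = 4e-21) {
  p <- list(S01 = S01, k01 = k01, k02 = k02, k0m2 = k0m2, k1 = k1,
            k21 = k21, k22 = k22, k3 = k3, R5Init = R5Init,
            R7Init = R7Init, V = V)
  rates <- unlist(p[c("k01", "k02", "k0m2", "k1", "k21", "k22", "k3")])
  if (any(rates <= 0)) stop("all rate constants must be positive")
  if (S01 < 0 || R5Init < 0 || R7Init < 0) stop("concentrations must be >= 0")
  if (V <= 0) stop("volume must be positive")
  p
}

#' Endosome cut-out-switch model (Rab5/Rab7 conversion)
#'
#' Seven mass-action channels over four species: active Rab5 (`R5`), active
#' Rab7 (`R7`), and the active/inactive effector forms `S0`/`S1` (the Rab7
#' effectors are identified with `S0`/`S1`, whose total `S01` is conserved):
#' \preformatted{
#'   S0           -> R5 + S0        (k01)
#'   S0 + 2 R7    -> S1 + 2 R7      (k02)
#'   S1           -> S0             (k0-2)
#'   R5           -> 0              (k1)
#'   R5           -> R7 + R5        (k21)
#'   S0 + 2 R7    -> S0 + 3 R7      (k22)
#'   R7           -> 0              (k3)
#' }
#' Rates are macroscopic and Avogadro-scaled to specific rates at volume
#' `V`; concentrations convert to copy numbers as `round(conc * V * N_A)`
#' (1 mol m^-3 at the default volume gives 2409 molecules).
#'
#' @param p Parameter list from [endosomeParams()].
#' @return A [ReactionNetwork-class] with 4 species and 7 reactions.
#' @export
makeEndosomeSwitch <- function(p = endosomeParams()) {
  reactionNetwork(
    data.frame(id = c("R5", "R7", "S0", "S1"),
               conc = c(p$R5Init, p$R7Init, p$S01, 0),
               diffusion = c(1e-21, 1e-21, NA, NA)),
    list(
      reaction(c(S0 = 1), c(R5 = 1, S0 = 1), rate = p$k01),
      reaction(c(S0 = 1, R7 = 2), c(S1 = 1, R7 = 2), rate = p$k02),
      reaction(c(S1 = 1), c(S0 = 1), rate = p$k0m2),
      reaction(c(R5 = 1), NULL, rate = p$k1),
      reaction(c(R5 = 1), c(R7 = 1, R5 = 1), rate = p$k21),
      reaction(c(S0 = 1, R7 = 2), c(S0 = 1, R7 = 3), rate = p$k22),
      reaction(c(R7 = 1), NULL, rate = p$k3)),
    volume = p$V, avogadroScaling = TRUE,
    name = "endosome_switch", units = "min")
}

#' Single delayed-conversion toy model
#'
#' One channel `A -> B` firing at rate `c` with delay `tau`, used to
#' exercise the delayed-reaction engine: with consuming semantics A is
#' removed at initiation and B appears `tau` later; with non-consuming
#' semantics the whole update happens at completion.
#'
#' @param c Specific initiation rate.
#' @param tau Delay duration (`0` reduces to an undelayed channel).
#' @param consuming Delay semantics.
#' @param nA0 Initial copy number of A.
#' @return A [ReactionNetwork-class].
#' @export
makeDelayedDegradation <- function(c = 1, tau = 1, consuming = TRUE, nA0 = 1) {
  stopifnot(tau >= 0, c > 0)
  reactionNetwork(
    data.frame(id = c("A", "B"), amount = c(nA0, 0)),
    list(reaction(c(A = 1), c(B = 1), rate = c, specific = TRUE,
                  delay = if (tau > 0) tau else NA_real_,
                  consuming = consuming)),
    volume = 1, name = "delayed_degradation")
}

#' Look up a built-in model by name
#'
#' Resolves CLI-style names `"builtin:<model>"` (or the bare model name)
#' to a factory call with default parameters. Available names:
#' `homoreaction`, `heteroreaction`, `cyclic_chain_N<k>`,
#' `colloidal_aggregation_N<k>`, `endosome`, `delayed_degradation`.
#'
#' @param name Model name, with or without the `"builtin:"` prefix.
#' @return A [ReactionNetwork-class].
#' @export
builtinModel <- function(name) {
  name <- sub("^builtin:", "", name)
  if (name == "homoreaction") return(makeHomoreaction())
  if (name == "heteroreaction") return(makeHeteroreaction())
  if (name == "endosome") return(makeEndosomeSwitch())
  if (name == "delayed_degradation") return(makeDelayedDegradation())
  m <- regmatches(name, regexec("^cyclic_chain_N([0-9]+)$", name))[[1]]
  if (length(m)) return(makeCyclicChain(as.integer(m[2])))
  m <- regmatches(name, regexec("^colloidal_aggregation_N([0-9]+)$", name))[[1]]
  if (length(m)) return(makeColloidalAggregation(as.integer(m[2])))
  stop("unknown builtin model '", name, "'; available: homoreaction, ",
       "heteroreaction, endosome, delayed_degradation, cyclic_chain_N<k>, ",
       "colloidal_aggregation_N<k>")
}
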
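#' Reaction dependency graph
#'
#' Directed graph over reaction channels with an edge `mu -> nu` iff firing
#' `mu` changes the copy number of at least one reactant of `nu` (the net
#' stoichiometric change of `mu` touches a reactant of `nu`). Self-edges
#' are included: a reaction that changes any of its own reactants depends
#' on itself. The maximum out-degree of this graph separates weakly coupled
#' networks (constant out-degree, e.g. the cyclic linear chain at 2) from
#' strongly coupled ones (out-degree growing with system size, e.g.
#' colloidal aggregation at `3N - 7`).
#'
#' @param net A [ReactionNetwork-class].
#' @return An [igraph::igraph] directed graph whose vertices are reaction
#'   indices (vertex names `"1"`, `"2"`, ...).
#' @examples
#' g <- buildDependencyGraph(makeCyclicChain(5))
#' maxOutDegree(g)
#' @export
buildDependencyGraph <- function(net) {
  M <- length(net@reactions)
  deltas <- lapply(net@reactions, reactionDelta)
  reactantSets <- lapply(net@reactions, function(rx) names(rx@reactants))
  edges <- integer(0)
  for (mu in seq_len(M)) {
    changed <- names(deltas[[mu]])[deltas[[mu]] != 0L]
    for (nu in seq_len(M)) {
      if (length(intersect(changed, reactantSets[[nu]])))
        edges <- c(edges, mu, nu)
    }
  }
  igraph::make_graph(edges = as.character(edges), isolates =
                       setdiff(as.character(seq_len(M)), as.character(edges)),
                     directed = TRUE)
}

#' Net stoichiometric change of a reaction
#'
#' @param rx A [Reaction-class].
#' @return Named integer vector of non-zero net changes (products minus
#'   reactants); empty for a pure catalytic channel.
#' @export
reactionDelta <- function(rx) {
  all <- union(names(rx@reactants), names(rx@products))
  d <- setNames(integer(length(all)), all)
  d[names(rx@products)] <- d[names(rx@products)] + rx@products
  d[names(rx@reactants)] <- d[names(rx@reactants)] - rx@reactants
  d[d != 0L]
}

#' Maximum out-degree of a dependency graph
#'
#' @param g Graph from [buildDependencyGraph()].
#' @return Integer maximum out-degree; 0 for an empty graph.
#' @export
maxOutDegree <- function(g) {
  if (igraph::vcount(g) == 0L) return(0L)
  as.integer(max(igraph::degree(g, mode = "out")))
}
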
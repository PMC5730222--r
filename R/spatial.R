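#' Per-jump diffusion propensity of a species in a subvolume
#'
#' `n * (D / h^2) * nNeighbors`: first-order jump rate of `n` molecules
#' with diffusion constant `D` out of a subvolume of edge length `h` with
#' `nNeighbors` open neighbor directions.
#'
#' @param n Copy number in the subvolume.
#' @param D Diffusion constant.
#' @param h Subvolume edge length (> 0).
#' @param nNeighbors Number of neighbor directions.
#' @return The total outward jump propensity.
#' @export
diffusionPropensity <- function(n, D, h, nNeighbors) {
  stopifnot(n >= 0, D >= 0, nNeighbors >= 0)
  if (h <= 0) stop("subvolume edge length h must be positive")
  n * (D / h^2) * nNeighbors
}

.gridNeighbors <- function(dims, boundary) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- function(x, y, z) (z - 1L) * nx * ny + (y - 1L) * nx + x
  nbrs <- vector("list", nx * ny * nz)
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    v <- idx(x, y, z)
    cand <- list(c(x - 1L, y, z), c(x + 1L, y, z),
                 c(x, y - 1L, z), c(x, y + 1L, z),
                 c(x, y, z - 1L), c(x, y, z + 1L))
    keepDim <- c(nx > 1L, nx > 1L, ny > 1L, ny > 1L, nz > 1L, nz > 1L)
    out <- integer(0)
    for (i in seq_along(cand)) {
      if (!keepDim[i]) next
      p <- cand[[i]]
      if (boundary == "periodic") {
        out <- c(out, idx(wrap(p[1], nx), wrap(p[2], ny), wrap(p[3], nz)))
      } else if (p[1] >= 1L && p[1] <= nx && p[2] >= 1L && p[2] <= ny &&
                 p[3] >= 1L && p[3] <= nz) {
        out <- c(out, idx(p[1], p[2], p[3]))
      }
    }
    nbrs[[v]] <- out
  }
  nbrs
}

#' Partition a well-mixed network onto a Cartesian subvolume grid
#'
#' Builds a [SubvolumeGrid-class] for the next-subvolume method: the
#' network's specific rates are rescaled to the subvolume volume
#' (`Omega_sub = Omega_total / nSubvolumes`, i.e. a channel of total
#' reactant order `o` gets its specific rate multiplied by
#' `nSubvolumes^(o-1)`), initial counts are distributed across subvolumes,
#' and per-species jump rates are `D / h^2` per neighbor direction.
#' Species without a diffusion constant are treated as immobile (jump rate
#' 0) with a warning when the grid has more than one subvolume.
#'
#' @param net A [ReactionNetwork-class] (no delayed channels).
#' @param dims Integer grid dimensions; scalars and length-2 vectors are
#'   padded to `(nx, ny, nz)`.
#' @param h Subvolume edge length (geometry of the jump rates; supplied
#'   independently of the volume used for rate rescaling).
#' @param boundary `"reflective"` (default, zero flux) or `"periodic"`.
#' @param init `"uniform"` (default: counts split as equally as possible,
#'   remainder to low-index subvolumes) or an integer matrix of
#'   per-subvolume counts (rows = subvolumes, columns = species).
#' @return A [SubvolumeGrid-class].
#' @examples
#' g <- buildGrid(makeEndosomeSwitch(), dims = 20, h = 1e-7)
#' @export
buildGrid <- function(net, dims, h, boundary = c("reflective", "periodic"),
                      init = "uniform") {
  boundary <- match.arg(boundary)
  rep <- validateNetwork(net)
  if (length(rep)) stop("invalid network: ", paste(rep, collapse = "; "))
  if (any(vapply(net@reactions, function(r) !is.na(r@delay), logical(1))))
    stop("the spatial engine does not support delayed reactions")
  dims <- as.integer(dims)
  if (length(dims) > 3L || any(dims < 1L)) stop("dims must be 1-3 positive integers")
  dims <- c(dims, rep(1L, 3L - length(dims)))
  if (h <= 0) stop("subvolume edge length h must be positive")
  nsub <- prod(dims)
  S <- length(net@species)

  # rescale rates to the subvolume volume
  cs <- networkSpecificRates(net)
  sub <- net
  sub@volume <- net@volume / nsub
  sub@reactions <- lapply(seq_along(net@reactions), function(i) {
    rx <- net@reactions[[i]]
    o <- sum(rx@reactants)
    rx@rate <- cs[i] * nsub^(o - 1)
    rx@rateIsSpecific <- TRUE
    rx
  })

  if (identical(init, "uniform")) {
    counts <- matrix(0L, nsub, S)
    for (s in seq_len(S)) {
      tot <- net@initialCounts[s]
      base <- tot %/% nsub
      extra <- tot %% nsub
      counts[, s] <- base + as.integer(seq_len(nsub) <= extra)
    }
  } else {
    counts <- init
    storage.mode(counts) <- "integer"
    if (nrow(counts) != nsub || ncol(counts) != S)
      stop("init matrix must be nSubvolumes x nSpecies")
  }
  colnames(counts) <- net@species

  jump <- ifelse(is.na(net@diffusion), 0, net@diffusion) / h^2
  if (nsub > 1L && any(is.na(net@diffusion)))
    warning("species without diffusion constants treated as immobile: ",
            paste(net@species[is.na(net@diffusion)], collapse = ", "))
  new("SubvolumeGrid", network = sub, dims = dims, h = h,
      boundary = boundary, counts = counts, jumpRates = as.numeric(jump),
      neighbors = .gridNeighbors(dims, boundary))
}

#' Next-subvolume reaction-diffusion simulation
#'
#' Runs the next-subvolume method on a [SubvolumeGrid-class]: every
#' subvolume is well mixed (reaction sampling via the per-subvolume
#' partial-propensity structure, or plain direct-method sampling with
#' `method = "dm"` for cross-validation), diffusion is a first-order jump
#' of one molecule to a uniformly chosen neighbor, and the subvolume with
#' the earliest absolute next-event time fires next (times redrawn for the
#' affected subvolumes after every event).
#'
#' @param grid A [SubvolumeGrid-class] from [buildGrid()].
#' @param tEnd,dt Recording grid as in [ssa()].
#' @param seed,trajIndex Random stream selectors as in [ssa()].
#' @param method Per-subvolume reaction sampler: `"pdm"` (default) or
#'   `"dm"`.
#' @return List with `times`, `counts` (array: time x subvolume x species,
#'   dimnames on the species axis), and `events`.
#' @export
simulateSpatial <- function(grid, tEnd, dt, seed = 1L, trajIndex = 0L,
                            method = c("pdm", "dm")) {
  method <- match.arg(method)
  stopifnot(tEnd > 0, dt > 0)
  res <- cpp_simulate_spatial(.engineModel(grid@network), grid@counts,
                              grid@jumpRates, grid@neighbors, method,
                              tEnd, dt, as.numeric(seed),
                              as.numeric(trajIndex))
  counts <- res$counts
  dimnames(counts) <- list(NULL, NULL, grid@network@species)
  list(times = res$times, counts = counts, events = res$events)
}

#' Kymograph of one species from a spatial simulation
#'
#' @param spatialResult Result of [simulateSpatial()].
#' @param species Species identifier.
#' @return Integer matrix (rows = time grid, columns = subvolumes).
#' @export
kymograph <- function(spatialResult, species) {
  if (!species %in% dimnames(spatialResult$counts)[[3]])
    stop("unknown species '", species, "'")
  spatialResult$counts[, , species]
}
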
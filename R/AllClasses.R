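#' @import methods
NULL

#' Single mass-action reaction channel
#'
#' A `Reaction` holds one irreversible mass-action channel. Reactant and
#' product stoichiometries are stored as named integer vectors (names are
#' species identifiers). Rate constants may be given either macroscopically
#' (converted to a specific probability rate at network build, see
#' [specificRate()]) or directly as a pre-scaled specific rate, which is how
#' the validation models state their lumped constants (e.g. `k1/V`).
#'
#' A channel may carry a time delay. A *consuming* delayed channel removes
#' its reactants at initiation and releases products after the delay; a
#' *non-consuming* one applies its whole stoichiometric update only at the
#' delayed completion.
#'
#' @slot reactants Named integer vector of reactant stoichiometries.
#' @slot products Named integer vector of product stoichiometries.
#' @slot rate Positive rate constant.
#' @slot rateIsSpecific Logical; `TRUE` when `rate` is already a specific
#'   probability rate (no volume scaling applied).
#' @slot delay Delay duration; `NA_real_` for an undelayed channel.
#' @slot delayConsuming Logical; semantics of the delayed channel.
#' @exportClass Reaction
setClass("Reaction", representation(
  reactants = "integer",
  products = "integer",
  rate = "numeric",
  rateIsSpecific = "logical",
  delay = "numeric",
  delayConsuming = "logical"
))

setValidity("Reaction", function(object) {
  msgs <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msgs <- c(msgs, "rate must be a single positive finite number")
  if (length(object@reactants) && (is.null(names(object@reactants)) ||
      any(!nzchar(names(object@reactants)))))
    msgs <- c(msgs, "reactants must be a named vector")
  if (length(object@products) && (is.null(names(object@products)) ||
      any(!nzchar(names(object@products)))))
    msgs <- c(msgs, "products must be a named vector")
  if (any(object@reactants < 1L)) msgs <- c(msgs, "reactant stoichiometries must be >= 1")
  if (any(object@products < 1L)) msgs <- c(msgs, "product stoichiometries must be >= 1")
  if (anyDuplicated(names(object@reactants)))
    msgs <- c(msgs, "duplicate reactant species (merge stoichiometries)")
  if (anyDuplicated(names(object@products)))
    msgs <- c(msgs, "duplicate product species (merge stoichiometries)")
  if (length(object@reactants) > 2L)
    msgs <- c(msgs, "more than two distinct reactant species")
  if (length(object@reactants) == 2L && sum(object@reactants > 1L) > 1L)
    msgs <- c(msgs, "two reactants with stoichiometry > 1")
  if (!is.na(object@delay) && object@delay < 0)
    msgs <- c(msgs, "delay must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Well-mixed chemical reaction network
#'
#' The central model object every engine consumes: an ordered species list
#' with integer initial copy numbers (concentrations are converted once at
#' build time), optional per-species diffusion constants (used only by the
#' spatial engine), an ordered list of [Reaction-class] channels, a
#' compartment volume and the unit convention used for macroscopic-to-
#' specific rate conversion.
#'
#' @slot name Model name (used in manifests and CLI output).
#' @slot species Character vector of unique species identifiers; this order
#'   indexes every count vector and trajectory column.
#' @slot initialCounts Integer vector of initial copy numbers, parallel to
#'   `species`.
#' @slot diffusion Numeric vector of diffusion constants (`NA` = unspecified,
#'   treated as immobile by the spatial engine), parallel to `species`.
#' @slot reactions List of [Reaction-class] objects.
#' @slot volume Positive compartment volume.
#' @slot avogadroScaling Logical; when `TRUE`, concentration-to-count
#'   conversion and rate scaling use `N_A * volume`, otherwise `volume`.
#' @slot units Time-unit label (documentation only; e.g. `"s"`, `"min"`).
#' @exportClass ReactionNetwork
setClass("ReactionNetwork", representation(
  name = "character",
  species = "character",
  initialCounts = "integer",
  diffusion = "numeric",
  reactions = "list",
  volume = "numeric",
  avogadroScaling = "logical",
  units = "character"
))

setValidity("ReactionNetwork", function(object) {
  rep <- validateNetwork(object)
  if (length(rep)) rep else TRUE
})

#' Partial-propensity factorization of a network state
#'
#' Reference (R-level) representation of the partial-propensity structure:
#' one row of partial propensities per species plus row 0 for source
#' (zeroth-order) channels, per-row sums `Lambda`, group sums
#' `Sigma = n * Lambda`, the total propensity `a0`, a lookup from (row,
#' column) to reaction index, and per-species update tables listing the
#' entries that depend on each species count. The compiled engines maintain
#' the same structure incrementally; this object exists for inspection and
#' for verifying incremental updates against full rebuilds.
#'
#' @slot rows List (length = number of species + 1) of numeric vectors of
#'   partial-propensity values; element 1 is the source row.
#' @slot rowRxns List parallel to `rows` giving the reaction index of each
#'   entry.
#' @slot Lambda Numeric vector of per-row sums.
#' @slot Sigma Numeric vector of group sums (`Sigma[1] = Lambda[1]`).
#' @slot a0 Total propensity.
#' @slot counts Integer state the structure was built for / updated to.
#' @slot dependents List (per species) of reaction indices whose partial
#'   propensity depends on that species' count.
#' @exportClass PartialPropensityState
setClass("PartialPropensityState", representation(
  rows = "list",
  rowRxns = "list",
  Lambda = "numeric",
  Sigma = "numeric",
  a0 = "numeric",
  counts = "integer",
  dependents = "list"
))

#' Recorded trajectory on a uniform time grid
#'
#' @slot times Numeric vector of recording times `k * dt`.
#' @slot counts Integer matrix, one row per recording time, one column per
#'   species (column names are species identifiers).
#' @slot species Character vector of species identifiers.
#' @slot method Engine name that produced the record.
#' @slot seed Integer master seed.
#' @slot events Total number of reaction (and diffusion) events fired.
#' @exportClass TrajectoryRecord
setClass("TrajectoryRecord", representation(
  times = "numeric",
  counts = "matrix",
  species = "character",
  method = "character",
  seed = "integer",
  events = "numeric"
))

setValidity("TrajectoryRecord", function(object) {
  msgs <- character()
  if (nrow(object@counts) != length(object@times))
    msgs <- c(msgs, "counts must have one row per recording time")
  if (is.unsorted(object@times, strictly = TRUE))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Collection of final states across Monte-Carlo samples
#'
#' @slot states Integer matrix, one row per sample, one column per species.
#' @slot species Character vector of species identifiers.
#' @slot method Engine name.
#' @slot seed Integer master seed.
#' @slot tEnd Simulated end time of every sample.
#' @exportClass SampleSet
setClass("SampleSet", representation(
  states = "matrix",
  species = "character",
  method = "character",
  seed = "integer",
  tEnd = "numeric"
))

#' Discrete probability distribution on 0..nMax
#'
#' @slot support Integer vector (contiguous, starting at 0).
#' @slot prob Numeric probabilities summing to 1.
#' @exportClass DiscretePDF
setClass("DiscretePDF", representation(
  support = "integer",
  prob = "numeric"
))

setValidity("DiscretePDF", function(object) {
  msgs <- character()
  if (length(object@support) != length(object@prob))
    msgs <- c(msgs, "support and prob must have equal length")
  if (any(object@prob < 0)) msgs <- c(msgs, "probabilities must be non-negative")
  if (length(object@prob) && abs(sum(object@prob) - 1) > 1e-10)
    msgs <- c(msgs, "probabilities must sum to 1 (tolerance 1e-10)")
  if (length(msgs)) msgs else TRUE
})

#' Stationary distribution of a truncated chemical master equation
#'
#' Joint distribution over the enumerated (reachable, truncated) state
#' space; use [marginalPdf()] to extract a per-species [DiscretePDF-class].
#'
#' @slot states Integer matrix of enumerated states (rows), one column per
#'   species.
#' @slot prob Numeric probabilities, parallel to rows of `states`.
#' @slot species Character vector of species identifiers.
#' @slot boundaryMass Probability mass on truncation-boundary states
#'   (diagnostic for truncation adequacy).
#' @exportClass CMEStationary
setClass("CMEStationary", representation(
  states = "matrix",
  prob = "numeric",
  species = "character",
  boundaryMass = "numeric"
))

#' Cartesian lattice of coupled well-mixed subvolumes
#'
#' Uniform grid for the next-subvolume reaction-diffusion method. The
#' per-subvolume reaction network carries specific rates rescaled to the
#' subvolume volume (`Omega_sub = Omega_total / nSubvolumes`); per-species
#' jump rates are `D / h^2` per neighbor direction.
#'
#' @slot network The per-subvolume [ReactionNetwork-class] (rates rescaled).
#' @slot dims Integer vector `(nx, ny, nz)`.
#' @slot h Subvolume edge length.
#' @slot boundary `"reflective"` or `"periodic"`.
#' @slot counts Integer matrix, one row per subvolume (row-major over the
#'   grid), one column per species.
#' @slot jumpRates Numeric per-species jump rate `D/h^2` per neighbor
#'   direction (0 for immobile species).
#' @slot neighbors List of integer vectors of neighbor subvolume indices.
#' @exportClass SubvolumeGrid
setClass("SubvolumeGrid", representation(
  network = "ReactionNetwork",
  dims = "integer",
  h = "numeric",
  boundary = "character",
  counts = "matrix",
  jumpRates = "numeric",
  neighbors = "list"
))

setValidity("SubvolumeGrid", function(object) {
  msgs <- character()
  nsub <- prod(object@dims)
  if (nrow(object@counts) != nsub)
    msgs <- c(msgs, "counts must have one row per subvolume")
  if (ncol(object@counts) != length(object@network@species))
    msgs <- c(msgs, "counts must have one column per species")
  if (!object@boundary %in% c("reflective", "periodic"))
    msgs <- c(msgs, "boundary must be 'reflective' or 'periodic'")
  if (any(object@jumpRates < 0)) msgs <- c(msgs, "jump rates must be >= 0")
  if (length(object@neighbors) != nsub)
    msgs <- c(msgs, "neighbor list must have one element per subvolume")
  if (length(msgs)) msgs else TRUE
})
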
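#' Avogadro's constant (mol^-1)
#' @keywords internal
.NA_CONST <- 6.02214076e23

#' Construct a reaction channel
#'
#' @param reactants Named integer/numeric vector of reactant stoichiometries
#'   (e.g. `c(A = 1, B = 2)`), or a reaction string such as
#'   `"S0 + 2 R7 -> S1 + 2 R7"` (in which case `products` is ignored).
#' @param products Named vector of product stoichiometries; empty vector or
#'   `NULL` for degradation to the sink.
#' @param rate Positive rate constant.
#' @param specific `TRUE` when `rate` is already a specific probability rate
#'   (lumped constant); `FALSE` (default) for a macroscopic rate converted at
#'   network build via [specificRate()].
#' @param delay Optional delay duration (`NA` for none).
#' @param consuming Semantics of a delayed channel: consuming (`TRUE`,
#'   default) removes reactants at initiation; non-consuming applies the
#'   whole update at completion.
#' @return A [Reaction-class] object.
#' @examples
#' reaction(c(A = 2), NULL, rate = 0.032, specific = TRUE)
#' reaction("S0 + 2 R7 -> S1 + 2 R7", rate = 100)
#' @export
reaction <- function(reactants, products = NULL, rate, specific = FALSE,
                     delay = NA_real_, consuming = TRUE) {
  if (is.character(reactants) && length(reactants) == 1L &&
      grepl("->", reactants, fixed = TRUE)) {
    sides <- parseReactionString(reactants)
    reactants <- sides$reactants
    products <- sides$products
  }
  new("Reaction",
      reactants = .asStoich(reactants), products = .asStoich(products),
      rate = as.numeric(rate), rateIsSpecific = isTRUE(specific),
      delay = as.numeric(delay), delayConsuming = isTRUE(consuming))
}

.asStoich <- function(x) {
  if (is.null(x) || length(x) == 0L) return(setNames(integer(0), character(0)))
  s <- as.integer(round(x))
  names(s) <- names(x)
  s
}

#' Parse one side-by-side reaction string
#'
#' Accepts `"A + 2 B -> C"` or `"2B"` style terms; `"0"` (or an empty side)
#' denotes the sink/source.
#' @param x A single string containing `"->"`.
#' @return List with named integer vectors `reactants` and `products`.
#' @export
parseReactionString <- function(x) {
  sides <- strsplit(x, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("reaction string must contain exactly one '->': ", x)
  list(reactants = .parseSide(sides[1]), products = .parseSide(sides[2]))
}

.parseSide <- function(s) {
  s <- trimws(s)
  if (s == "" || s == "0") return(setNames(integer(0), character(0)))
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- integer(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]*)\\s*([A-Za-z_][A-Za-z0-9_.-]*)$", tm))[[1]]
    if (length(m) == 0L) stop("cannot parse reaction term: '", tm, "'")
    st <- if (m[2] == "") 1L else as.integer(m[2])
    sp <- m[3]
    if (sp %in% names(out)) out[sp] <- out[sp] + st else out[sp] <- st
  }
  out
}

#' Construct a well-mixed reaction network
#'
#' Species are given as a data frame with columns `id` and exactly one of
#' `amount` (integer copy number) or `conc` (concentration, converted once
#' here: `counts = round(conc * Omega)` with `Omega = N_A * volume` under
#' Avogadro scaling, else `volume`; rounding half-up). An optional
#' `diffusion` column carries per-species diffusion constants for the
#' spatial engine.
#'
#' @param species Data frame with columns `id`, and `amount` and/or `conc`
#'   (exactly one non-`NA` per species), optionally `diffusion`.
#' @param reactions List of [Reaction-class] objects (see [reaction()]).
#' @param volume Positive compartment volume.
#' @param avogadroScaling Use `N_A * volume` as the scaling volume `Omega`.
#' @param name Model name.
#' @param units Time-unit label (documentation only).
#' @return A validated [ReactionNetwork-class].
#' @examples
#' net <- reactionNetwork(
#'   data.frame(id = "A", amount = 25),
#'   list(reaction(c(A = 2), NULL, rate = 0.032, specific = TRUE),
#'        reaction(NULL, c(A = 1), rate = 10, specific = TRUE)),
#'   volume = 1)
#' @export
reactionNetwork <- function(species, reactions, volume = 1,
                            avogadroScaling = FALSE, name = "model",
                            units = "s") {
  stopifnot(is.data.frame(species), "id" %in% names(species))
  ids <- as.character(species$id)
  amount <- if ("amount" %in% names(species)) species$amount else rep(NA_real_, length(ids))
  conc <- if ("conc" %in% names(species)) species$conc else rep(NA_real_, length(ids))
  omega <- if (isTRUE(avogadroScaling)) .NA_CONST * volume else volume
  counts <- integer(length(ids))
  for (i in seq_along(ids)) {
    hasA <- !is.na(amount[i]); hasC <- !is.na(conc[i])
    if (hasA == hasC)
      stop("species '", ids[i], "': give exactly one of amount or conc")
    counts[i] <- if (hasA) as.integer(round(amount[i]))
                 else as.integer(floor(conc[i] * omega + 0.5))
  }
  diff <- if ("diffusion" %in% names(species)) as.numeric(species$diffusion)
          else rep(NA_real_, length(ids))
  net <- new("ReactionNetwork",
             name = name, species = ids, initialCounts = counts,
             diffusion = diff, reactions = reactions,
             volume = as.numeric(volume),
             avogadroScaling = isTRUE(avogadroScaling), units = units)
  net
}

#' Validate a reaction network
#'
#' Returns a character vector of violations (empty means the network is
#' simulable): unknown species references, more than two distinct reactant
#' species, two reactants both with stoichiometry above one, non-positive
#' rates, negative counts/volume/delays, duplicate species identifiers.
#'
#' @param net A [ReactionNetwork-class] (validity is *not* assumed).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validateNetwork <- function(net) {
  msgs <- character()
  ids <- net@species
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate species identifiers")
  if (length(net@initialCounts) != length(ids))
    msgs <- c(msgs, "initialCounts length differs from species count")
  if (any(net@initialCounts < 0)) msgs <- c(msgs, "negative initial counts")
  if (length(net@diffusion) != length(ids))
    msgs <- c(msgs, "diffusion length differs from species count")
  if (any(!is.na(net@diffusion) & net@diffusion < 0))
    msgs <- c(msgs, "negative diffusion constant")
  if (length(net@volume) != 1L || !is.finite(net@volume) || net@volume <= 0)
    msgs <- c(msgs, "volume must be a single positive number")
  for (i in seq_along(net@reactions)) {
    rx <- net@reactions[[i]]
    v <- validObject(rx, test = TRUE)
    if (!isTRUE(v))
      msgs <- c(msgs, paste0("reaction ", i, ": ", v))
    unknown <- setdiff(c(names(rx@reactants), names(rx@products)), ids)
    if (length(unknown))
      msgs <- c(msgs, paste0("reaction ", i, ": unknown species ",
                             paste(unknown, collapse = ", ")))
  }
  msgs
}

#' Macroscopic-to-specific rate conversion
#'
#' Converts a macroscopic mass-action rate constant `k` into the specific
#' probability rate `c = k * Omega^(1 - o) * prod(s_i!)`, where `o` is the
#' total reactant order (sum of stoichiometries), `s_i` the per-species
#' stoichiometries and `Omega = N_A * volume` under Avogadro scaling, else
#' `volume`. The propensity is then `a = c * prod(choose(n_i, s_i))`, which
#' reproduces the deterministic rate law `v = k * prod([X_i]^s_i)` in the
#' dilute limit. Reactions flagged `rateIsSpecific` are returned unchanged.
#'
#' @param rx A [Reaction-class].
#' @param volume Positive compartment volume.
#' @param avogadroScaling Use `N_A * volume` as `Omega`.
#' @return The specific probability rate `c`.
#' @examples
#' ## trimolecular S0 + 2 R7, k = 100, V = 4e-21 with Avogadro scaling
#' rx <- reaction(c(S0 = 1, R7 = 2), c(S1 = 1, R7 = 2), rate = 100)
#' specificRate(rx, 4e-21, TRUE)
#' @export
specificRate <- function(rx, volume, avogadroScaling = FALSE) {
  v <- validObject(rx, test = TRUE)
  if (!isTRUE(v)) stop("invalid reaction: ", paste(v, collapse = "; "))
  if (rx@rateIsSpecific) return(rx@rate)
  if (volume <= 0) stop("volume must be positive")
  omega <- if (isTRUE(avogadroScaling)) .NA_CONST * volume else volume
  o <- sum(rx@reactants)
  rx@rate * omega^(1 - o) * prod(factorial(rx@reactants))
}

#' Mass-action propensity of a reaction
#'
#' `a = c * prod(choose(n_i, s_i))` over distinct reactants: the specific
#' probability rate times the reaction degeneracy (number of distinct
#' reactant combinations); zero whenever any reactant count falls below its
#' stoichiometry.
#'
#' @param rx A [Reaction-class].
#' @param counts Named (or network-ordered) integer vector of copy numbers.
#' @param c Specific probability rate.
#' @return The propensity (non-negative).
#' @export
propensity <- function(rx, counts, c) {
  a <- c
  rs <- rx@reactants
  for (i in seq_along(rs)) {
    n <- counts[[names(rs)[i]]]
    a <- a * choose(n, rs[[i]])
  }
  max(a, 0)
}

#' Partial propensity and pivot species of a reaction
#'
#' Factors the propensity as `a = n_pivot * pi` over a designated pivot
#' reactant. Conventions: a source channel has pivot `"source"` and
#' `pi = c` (then `a = pi`); a single reactant A with stoichiometry `s` has
#' pivot A and `pi = c * choose(n_A - 1, s - 1) / s` (so `pi = c` for a
#' unimolecular channel and `pi = c * (n_A - 1) / 2` for a homodimer); for
#' two distinct reactants the pivot is the stoichiometry-one species when
#' the other has stoichiometry above one, otherwise the reactant with the
#' smaller species index, and `pi = c * choose(n_other, s_other)`.
#'
#' @param rx A [Reaction-class].
#' @param counts Named integer vector of copy numbers.
#' @param c Specific probability rate.
#' @param speciesOrder Character vector fixing species indices for the
#'   smaller-index tie-break (defaults to the order of `counts`).
#' @return List with elements `pivot` (species id or `"source"`) and
#'   `value` (`pi`).
#' @export
partialPropensity <- function(rx, counts, c, speciesOrder = names(counts)) {
  rs <- rx@reactants
  if (length(rs) == 0L) return(list(pivot = "source", value = c))
  if (length(rs) == 1L) {
    sp <- names(rs); s <- rs[[1]]
    n <- counts[[sp]]
    # pi = c for a unimolecular channel regardless of n; for s > 1 the
    # factored form c * choose(n-1, s-1) / s is clamped to 0 below n = 1
    val <- if (s == 1L) c
           else if (n >= 1L) c * choose(n - 1, s - 1) / s else 0
    return(list(pivot = sp, value = val))
  }
  ids <- names(rs)
  if (rs[[1]] > 1L) {
    pivot <- ids[2]; other <- ids[1]; so <- rs[[1]]
  } else if (rs[[2]] > 1L) {
    pivot <- ids[1]; other <- ids[2]; so <- rs[[2]]
  } else {
    ord <- match(ids, speciesOrder)
    pivot <- ids[which.min(ord)]; other <- ids[which.max(ord)]; so <- 1L
  }
  list(pivot = pivot, value = c * choose(counts[[other]], so))
}

#' @describeIn reactionNetwork Species identifiers of a network.
#' @export
speciesIds <- function(net) net@species

#' @describeIn reactionNetwork Initial copy-number vector (named).
#' @export
initialCounts <- function(net) setNames(net@initialCounts, net@species)

#' @describeIn reactionNetwork List of reaction channels.
#' @export
reactions <- function(net) net@reactions

#' @describeIn reactionNetwork Number of reaction channels.
#' @export
nReactions <- function(net) length(net@reactions)

#' Specific rates of all channels of a network
#'
#' Applies [specificRate()] to every channel using the network's volume and
#' scaling convention.
#' @param net A [ReactionNetwork-class].
#' @return Numeric vector of specific probability rates.
#' @export
networkSpecificRates <- function(net) {
  vapply(net@reactions, specificRate, numeric(1),
         volume = net@volume, avogadroScaling = net@avogadroScaling)
}

#' Total propensity of a network state
#'
#' Direct (unfactorized) sum of channel propensities; used as the oracle for
#' the partial-propensity bookkeeping.
#' @param net A [ReactionNetwork-class].
#' @param counts Named counts; defaults to the initial state.
#' @return Sum of propensities.
#' @export
totalPropensity <- function(net, counts = initialCounts(net)) {
  cs <- networkSpecificRates(net)
  sum(vapply(seq_along(net@reactions), function(i)
    propensity(net@reactions[[i]], counts, cs[i]), numeric(1)))
}

.formatReaction <- function(rx) {
  side <- function(v) {
    if (length(v) == 0L) return("0")
    paste(ifelse(v > 1L, paste(v, names(v)), names(v)), collapse = " + ")
  }
  s <- paste(side(rx@reactants), "->", side(rx@products))
  tag <- if (rx@rateIsSpecific) "c" else "k"
  s <- paste0(s, "  [", tag, " = ", format(rx@rate), "]")
  if (!is.na(rx@delay))
    s <- paste0(s, " delay ", format(rx@delay),
                if (rx@delayConsuming) " (consuming)" else " (non-consuming)")
  s
}

setMethod("show", "Reaction", function(object) {
  cat("Reaction:", .formatReaction(object), "\n")
})

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork '", object@name, "': ",
      length(object@species), " species, ",
      length(object@reactions), " reactions\n", sep = "")
  cat("  volume:", format(object@volume),
      if (object@avogadroScaling) "(Avogadro scaling)" else "", "\n")
  cat("  species:", paste0(object@species, "=", object@initialCounts,
                           collapse = ", "), "\n")
  for (rx in object@reactions) cat("  ", .formatReaction(rx), "\n", sep = "")
})

setMethod("show", "TrajectoryRecord", function(object) {
  cat("TrajectoryRecord (", object@method, "): ",
      length(object@times), " time points, ",
      length(object@species), " species, ",
      object@events, " events, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "SampleSet", function(object) {
  cat("SampleSet (", object@method, "): ", nrow(object@states),
      " samples at t = ", object@tEnd, ", species ",
      paste(object@species, collapse = ", "), "\n", sep = "")
})

setMethod("show", "DiscretePDF", function(object) {
  cat("DiscretePDF on 0..", max(object@support), ", mean ",
      format(sum(object@support * object@prob)), "\n", sep = "")
})

setMethod("show", "SubvolumeGrid", function(object) {
  cat("SubvolumeGrid ", paste(object@dims, collapse = "x"),
      " (", object@boundary, "), h = ", format(object@h),
      ", ", length(object@network@species), " species\n", sep = "")
})
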
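# SBML Level 2 Version 4 import/export on xml2. Stochastic parameters
# (specific-vs-macroscopic rate, delay, diffusion) live in a dedicated
# annotation namespace; when a reaction carries no annotation, the first
# local kinetic-law parameter is used as its macroscopic rate.

.SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
.PPSIM_NS <- "http://ppsim.r-pkg.invalid/annotation/v1"

#' Export a network to SBML Level 2 Version 4
#'
#' Species initial amounts, reaction stoichiometries and the compartment
#' volume map onto standard SBML elements; the rate constant (with its
#' specific/macroscopic flag), optional delay and per-species diffusion
#' constants are written as annotation elements in the package's
#' annotation namespace. Reversible reactions do not exist in this model
#' class, so every reaction is written `reversible="false"`.
#'
#' @param net A [ReactionNetwork-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
exportSBML <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  L <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
         sprintf('<sbml xmlns="%s" xmlns:pp="%s" level="2" version="4">',
                 .SBML_NS, .PPSIM_NS),
         sprintf('  <model id="%s">', gsub("[^A-Za-z0-9_]", "_", net@name)),
         '    <listOfCompartments>',
         sprintf('      <compartment id="cell" size="%s"/>',
                 format(net@volume, digits = 17)),
         '    </listOfCompartments>',
         '    <listOfSpecies>')
  for (i in seq_along(net@species)) {
    ann <- if (!is.na(net@diffusion[i]))
      sprintf('><annotation><pp:diffusion value="%s"/></annotation></species>',
              format(net@diffusion[i], digits = 17)) else "/>"
    L <- c(L, sprintf('      <species id="%s" compartment="cell" initialAmount="%d"%s',
                      esc(net@species[i]), net@initialCounts[i], ann))
  }
  L <- c(L, '    </listOfSpecies>', '    <listOfReactions>')
  for (j in seq_along(net@reactions)) {
    rx <- net@reactions[[j]]
    L <- c(L, sprintf('      <reaction id="r%d" reversible="false">', j))
    ann <- sprintf('        <annotation><pp:rate value="%s" specific="%s"/>%s</annotation>',
                   format(rx@rate, digits = 17),
                   tolower(as.character(rx@rateIsSpecific)),
                   if (!is.na(rx@delay))
                     sprintf('<pp:delay value="%s" consuming="%s"/>',
                             format(rx@delay, digits = 17),
                             tolower(as.character(rx@delayConsuming)))
                   else "")
    L <- c(L, ann)
    refs <- function(v, tag) {
      if (length(v) == 0L) return(character(0))
      c(sprintf('        <listOf%ss>', tag),
        sprintf('          <%s species="%s" stoichiometry="%d"/>',
                tag, esc(names(v)), unname(v)),
        sprintf('        </listOf%ss>', tag))
    }
    L <- c(L, refs(rx@reactants, "speciesReference"))
    # products need a distinct wrapper name in SBML
    if (length(rx@products)) {
      L <- c(L, '        <listOfProducts>',
             sprintf('          <speciesReference species="%s" stoichiometry="%d"/>',
                     esc(names(rx@products)), unname(rx@products)),
             '        </listOfProducts>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>', '  </model>', '</sbml>')
  # fix reactant wrapper naming: listOfSpeciesReferences -> listOfReactants
  L <- gsub("listOfspeciesReferences", "listOfReactants", L)
  writeLines(L, path)
  invisible(path)
}

#' Import an SBML Level 2 model
#'
#' Reads species from `listOfSpecies` (`initialAmount`, or
#' `initialConcentration` times the compartment size with Avogadro
#' scaling) and one reaction per `listOfReactions` entry. The rate
#' constant is taken from the package's annotation namespace when
#' present (`rate`, optional `delay`, per-species `diffusion`), falling
#' back to the first local kinetic-law parameter, read as a macroscopic
#' rate. Reactions marked `reversible="true"` are rejected with an
#' instruction to split them into two irreversible channels.
#'
#' @param path SBML file path.
#' @param avogadroScaling Scaling convention for concentration-to-count
#'   conversion and macroscopic rates (default `TRUE`).
#' @return A validated [ReactionNetwork-class].
#' @export
importSBML <- function(path, avogadroScaling = TRUE) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[["d1"]], pp = .PPSIM_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) stop("no <model> element in ", path)
  comp <- xml2::xml_find_first(model, ".//s:compartment", ns)
  volume <- if (inherits(comp, "xml_missing")) 1
            else as.numeric(xml2::xml_attr(comp, "size") %||% "1")
  if (is.na(volume)) volume <- 1
  omega <- if (avogadroScaling) .NA_CONST * volume else volume

  spNodes <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  if (length(spNodes) == 0L) stop("no species in ", path)
  ids <- xml2::xml_attr(spNodes, "id")
  amounts <- rep(NA_real_, length(ids))
  diffs <- rep(NA_real_, length(ids))
  for (i in seq_along(spNodes)) {
    ia <- xml2::xml_attr(spNodes[[i]], "initialAmount")
    ic <- xml2::xml_attr(spNodes[[i]], "initialConcentration")
    if (!is.na(ia)) amounts[i] <- as.numeric(ia)
    else if (!is.na(ic)) amounts[i] <- floor(as.numeric(ic) * omega + 0.5)
    else stop("species '", ids[i], "' has neither initialAmount nor initialConcentration")
    dn <- xml2::xml_find_first(spNodes[[i]], ".//pp:diffusion", ns)
    if (!inherits(dn, "xml_missing"))
      diffs[i] <- as.numeric(xml2::xml_attr(dn, "value"))
  }

  rxNodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rxns <- vector("list", length(rxNodes))
  for (j in seq_along(rxNodes)) {
    node <- rxNodes[[j]]
    rid <- xml2::xml_attr(node, "id") %||% as.character(j)
    if (identical(tolower(xml2::xml_attr(node, "reversible") %||% "false"), "true"))
      stop("reaction '", rid, "' is reversible; split it into two ",
           "irreversible reactions")
    readRefs <- function(which) {
      refs <- xml2::xml_find_all(node, sprintf("./s:listOf%s/s:speciesReference", which), ns)
      if (length(refs) == 0L) return(setNames(integer(0), character(0)))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      setNames(as.integer(round(st)), xml2::xml_attr(refs, "species"))
    }
    reac <- readRefs("Reactants")
    prod <- readRefs("Products")
    rateNode <- xml2::xml_find_first(node, ".//pp:rate", ns)
    delayNode <- xml2::xml_find_first(node, ".//pp:delay", ns)
    if (!inherits(rateNode, "xml_missing")) {
      rate <- as.numeric(xml2::xml_attr(rateNode, "value"))
      specific <- identical(tolower(xml2::xml_attr(rateNode, "specific") %||% "false"), "true")
    } else {
      par <- xml2::xml_find_first(node, ".//s:kineticLaw//s:parameter", ns)
      if (inherits(par, "xml_missing"))
        stop("reaction '", rid, "' has no rate annotation and no local ",
             "kinetic-law parameter")
      rate <- as.numeric(xml2::xml_attr(par, "value"))
      specific <- FALSE
    }
    if (is.na(rate)) stop("reaction '", rid, "' has a non-numeric rate")
    delay <- NA_real_; consuming <- TRUE
    if (!inherits(delayNode, "xml_missing")) {
      delay <- as.numeric(xml2::xml_attr(delayNode, "value"))
      consuming <- identical(tolower(xml2::xml_attr(delayNode, "consuming") %||% "true"), "true")
    }
    rxns[[j]] <- reaction(reac, prod, rate = rate, specific = specific,
                          delay = delay, consuming = consuming)
  }
  mid <- xml2::xml_attr(model, "id") %||% "sbml_model"
  net <- reactionNetwork(data.frame(id = ids, amount = amounts,
                                    diffusion = diffs),
                         rxns, volume = volume,
                         avogadroScaling = avogadroScaling, name = mid)
  repv <- validateNetwork(net)
  if (length(repv)) stop("invalid SBML model in ", path, ": ",
                         paste(repv, collapse = "; "))
  net
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
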
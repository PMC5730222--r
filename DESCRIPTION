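Package: ppsim
Title: Partial-Propensity Stochastic Simulation of Chemical Reaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation of mass-action chemical reaction
    networks using the partial-propensity family of algorithms: Gillespie's
    direct method (DM) as a reference, the partial-propensity direct method
    (PDM), its sorting variant (SPDM), composition-rejection sampling
    (PSSA-CR), delayed reactions with consuming and non-consuming semantics
    (dPDM), and stochastic reaction-diffusion on uniform Cartesian grids via
    the next-subvolume method. Includes analytic and brute-force
    chemical-master-equation references for validation, Kullback-Leibler
    convergence diagnostics, built-in benchmark and validation networks, a
    stochastic model of early-to-late endosome conversion (Rab5/Rab7 cut-out
    switch), SBML Level 2 import/export, a native model format, and
    command-line simulator and analyzer tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
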
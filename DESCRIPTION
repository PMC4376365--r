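Package: colonyFBA
Title: Spatially Resolved Dynamic Flux Balance Analysis of Bacterial Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid three-dimensional reaction-diffusion / flux-balance-analysis
    simulator of dense bacterial colony growth on agar. Substrate fields (glucose,
    oxygen, acetate) diffuse on a cubic lattice with site-type-dependent and
    crowding-hindered diffusivities; cells take up substrates by Michaelis-Menten
    kinetics, and their metabolism and growth are predicted per lattice site by
    flux balance analysis served from precomputed, interpolated lookup tables.
    Colony volume grows exponentially and relaxes by iterative expansion into
    neighboring sites. Cells switch between glucose- and acetate-consuming
    regulatory states at substrate-dependent rates calibrated against batch
    culture data, reproducing the acetate switch and emergent acetate
    crossfeeding between anoxic interior and oxygenated shell subpopulations.
    Includes an optional molecular-crowding constraint on the flux solutions,
    a self-contained toy metabolic model, synthetic batch-data generators, and
    analytic diffusion oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
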
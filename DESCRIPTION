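Package: pmfassoc
Title: Association Thermodynamics from Umbrella-Sampling Free-Energy Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the solution association of carboxylic acids in
    nonpolar solvents from one-dimensional free-energy profiles. Generates
    synthetic umbrella-sampling window data from parametric model potentials of
    mean force (PMF), reconstructs the unbiased PMF with the weighted histogram
    analysis method (WHAM) including Monte Carlo bootstrap uncertainty and
    overlap/convergence diagnostics, converts PMF wells into dissociation free
    energies and equilibrium constants under selectable standard states, fits
    the integrated Van't Hoff equation to K(T) data, and solves coupled
    monomer/dimer/hydrate speciation equilibria.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
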
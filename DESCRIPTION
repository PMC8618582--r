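Package: chromoCA
Title: Chromosome Folding and Intrachromosomal Aberration Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained heteropolymer modelling of interphase chromosomes
    and Monte Carlo simulation of intrachromosomal exchange aberrations
    (cis-translocations). Fits per-pair attraction potentials of a 100-kb
    bead chain to a target Hi-C contact map by iterative inverse
    optimization, generates Langevin-dynamics conformational ensembles,
    and simulates translocation breakpoint distributions arising from
    nuclease-, radiation- and spontaneous DNA double-strand breaks under
    the contact-first and breakage-first mechanisms. Includes pair-distance
    (damage heterogeneity) analysis, dose-response decomposition by lesion
    origin, conformational-transition scenarios, pseudo-4C profile
    extraction, and a synthetic fixture generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
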
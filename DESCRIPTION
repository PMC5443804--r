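Package: smcomplex
Title: Single-Molecule Analysis of Peptide Complex Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the assembly of amyloid-beta hairpin and
    monomer peptides from single-molecule experiments and coarse-grained
    simulation. Implements worm-like-chain fitting of AFM force-distance
    curves with rupture-event detection and contour-length filtering,
    dwell-time (lifetime) extraction from single-molecule fluorescence
    traces with lognormal fitting, particle-height and cross-section
    statistics on AFM topographs, dihedral principal-component free-energy
    landscapes, and a Metropolis Monte Carlo pulling simulator for
    coarse-grained Go-model dimers with virtual springs. Ships synthetic
    generators for every input so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    utils,
    Rcpp,
    EBImage,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
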
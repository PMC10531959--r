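Package: nmr2dock
Title: Ligand Pose Determination from Semi-Ambiguous NMR Methyl Distance Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines protein-fragment binding poses from semi-ambiguous
    intermolecular NOE distance restraints, in which the ligand protons are
    assigned but the receptor methyl groups are anonymous. The package
    enumerates methyl assignment combinations under partial-assignment
    constraints, optimizes a rigid ligand pose against upper/lower distance
    bounds by multi-start simulated annealing, ranks candidate structures by a
    violation target function, and validates the top pose through the target
    function contrast with the first distinct alternative pose. Includes
    ligand/binding-site topology diagnostics that predict convergence, a
    seeded synthetic benchmark generator, restraint file I/O, and
    tidyverse-style accessors and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
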
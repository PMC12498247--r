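Package: confsel
Title: Feature-Based Conformer Selection and Conformer-Weighted Descriptors
    for Bisphosphine Pd(II) Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for pruning conformer ensembles of bisphosphine-ligated
    palladium(II) dichloride complexes and building conformer-weighted
    molecular feature sets.  Reads multi-frame XYZ ensembles, computes
    coordinate-based steric and geometric descriptors (bite angle, percent
    buried volume, equivalent cone angle from solid angles, solvent
    accessible surface area, molecular volume), selects representative
    conformers by equidistant coverage of an energy or feature axis,
    aggregates per-conformer features into Boltzmann-weighted, minimum,
    maximum, mean and lowest-energy statistics, and feeds the result into
    forward stepwise multivariate linear regression or decision-tree
    regression workflows with permutation feature importance and
    cross-validation diagnostics.  A synthetic generator produces toy
    PdCl2(P^P) geometries and planted-relationship datasets for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
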
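Package: sqdimer
Title: Excitonic Coupling and Geometry of DNA-Templated Squaraine Dye Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for squaraine dye dimers templated on DNA
    Holliday junctions. Computes the exciton hopping parameter J between two
    dyes in the extended dipole approximation, per-frame dimer orientation
    metrics (center distance R, oblique angle, slip angle, orientation factor
    kappa-squared, packing factor kappa-prime), residue-residue contact
    probability maps with a center-of-mass cutoff, and ensemble summaries by
    time-series averaging or greedy GROMOS clustering of frames. A synthetic
    two-dye trajectory generator with a mock four-arm junction scaffold
    provides ground-truth data for testing every stage without molecular
    dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
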
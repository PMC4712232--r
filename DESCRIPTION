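Package: ipmap
Title: A-Priori-Model-Free Inverse Potential Mapping of Epicardial Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for electrocardiographic
    imaging (inverse potential mapping) without a-priori activation models.
    Generates synthetic multi-compartment thorax anatomy (torso, lungs, liver,
    spleen, heart) as closed triangulated surfaces, simulates cardiac
    activation by visibility-constrained shortest-path propagation
    (Moller-Trumbore ray casting and Floyd-Warshall all-pairs shortest paths)
    with location-specific activation curves, computes body-surface potentials
    through a boundary-element transfer matrix for the piecewise-homogeneous
    volume conductor, samples configurable electrode arrays, and reconstructs
    epicardial potentials by zero-order Tikhonov regularization with L-curve
    selection of the regularization strength. Includes the evaluation metrics
    (source correlation, forward-reconstructed ECG consistency, pacing-site
    localization error, point-spread threshold test) and packaged experiments
    comparing surrounding versus concentrated electrode configurations and
    localizing simulated pacing sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
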
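Package: transpath
Title: Transition Path Analysis and Quasi-Potential Reconstruction from
    Single-Cell Trajectories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of cell phenotypic transitions recorded as single-cell
    trajectories in a reduced morphology/texture feature space. Identifies
    reactive trajectories connecting two attractor regions, discovers
    parallel transition channels with self-organizing-map transition
    networks and dynamic-time-warping clustering, reconstructs
    one-dimensional reaction coordinates with a revised finite-temperature
    string method, estimates drift, diffusion and quasi-potentials along
    each coordinate, tests Markovianity with the Chapman-Kolmogorov test,
    and predicts stationary distributions with a one-dimensional
    Fokker-Planck solver. A seeded Langevin simulator on analytic
    landscapes provides ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
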
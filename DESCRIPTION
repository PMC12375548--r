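Package: shoulderkin
Title: Personalized Closed-Chain Shoulder Kinematic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds open-chain scapulothoracic (3/4/5 degree-of-freedom) and
    closed-chain shoulder (6/7 degree-of-freedom) kinematic models, and
    personalizes their joint parameters and body scale factors against marker
    trajectories using a bi-level nonlinear least-squares procedure: an outer
    optimization over joint frame offsets, scales, and constraint locations,
    with repeated marker-based inverse kinematics as the inner solve.  Includes
    synthetic gold-standard marker generation from 6-DOF pose trajectories,
    TRC marker-file input/output, sinusoidal skin-marker noise simulation,
    leave-one-out cross-validation over motion tasks, and reduction of the
    scapular translation coordinate through a linear coordinate coupler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
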
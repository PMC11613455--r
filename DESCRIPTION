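Package: crowdflow
Title: Transport Properties and Colloid-Theory Interaction Analysis for
    Crowded Protein Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of translational and rotational diffusion, shear
    viscosity, and protein-protein interaction strength in crowded
    macromolecular solutions. Implements Green-Kubo shear viscosity from
    replicate pressure-tensor fluctuations with an uncertainty-weighted
    double-exponential extrapolation protocol, mean-square-displacement
    and P2 orientational-autocorrelation diffusion estimators with
    periodic-box finite-size and water-model corrections, contact and
    cluster kinetics with triple-exponential survival fits, second virial
    coefficients from center-of-mass radial distribution functions mapped
    to Baxter adhesive-hard-sphere stickiness and dissociation constants,
    and concentration-dependence models (Einstein, quadratic, Mooney,
    effective-cluster-size). Includes Brownian-dynamics, rotational-walk,
    Ornstein-Uhlenbeck stress and contact-timeline generators with known
    ground truth so every estimator is verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
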
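Package: droughtjac
Title: Stress Susceptibility Indices and Network-Constrained Biochemical
    Jacobian Inference from Metabolomics Covariance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for data-driven analysis of drought tolerance in crop
    genotype panels. Computes the Fischer-Maurer stress susceptibility
    index (SSI) from paired well-watered and drought yields and classifies
    genotypes into tolerance/production quadrants; screens metabolite
    relative abundances for Pearson association with SSI; and infers the
    biochemical Jacobian of a metabolic network from the covariance of
    log-transformed metabolite abundances by solving the inverse Lyapunov
    equation J*C + C*J' = -2*D under a network sparsity constraint, with
    Monte-Carlo median aggregation over random noise matrices and
    differential (log-ratio) comparison of Jacobians between genotype
    groups. Includes seeded synthetic-data generators (stable Jacobians on
    toy networks, stationary log-normal abundance samples, yield panels
    with planted tolerance classes, SSI-correlated metabolomes) so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
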
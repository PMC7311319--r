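Package: phagefilm
Title: Individual-Based Simulation of Lytic Phage-Biofilm Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An individual-based model of lytic bacteriophage attack on
    surface-attached bacterial biofilms. Discrete susceptible and
    phage-resistant bacteria grow on a lattice under a quasi-steady
    reaction-diffusion nutrient field with Monod uptake; individually
    tracked virions move by an impeded lattice random walk with advective
    removal, adsorb to biomass, infect hosts, and burst after a latent
    period. Includes biofilm erosion, detachment of disconnected biomass,
    shoving relaxation, phage pulse events, replicate sweeps over nutrient
    availability and initial strain frequency, and tidy summaries of
    frequency-dependent selection for phage resistance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
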
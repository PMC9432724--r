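Package: mitoloc
Title: Stochastic Simulation of Co-Translational mRNA Localization to
    Mitochondria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative modelling of mitochondrial targeting sequence
    (MTS) mediated mRNA localization to the mitochondrial surface in
    budding yeast.  Provides an exactly-solved four-state kinetic model of
    competence switching and spatial transport, a Gillespie simulator of
    ribosome loading, elongation with steric exclusion, MTS translation
    and maturation, an event-driven propagator for radial diffusion among
    concentric cylindrical shells surrounding a mitochondrial tubule, a
    coupled translation-diffusion trajectory simulator with irreversible
    competent binding, closed-form predictors (mean exposed and mature
    MTS counts, MTS exposure times, diffusive search times), estimation
    of gene-specific initiation and elongation rates from protein-per-mRNA
    and ribosome-occupancy measurements, and a synthetic gene-cohort
    generator for the conditionally and constitutively localized gene
    groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
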
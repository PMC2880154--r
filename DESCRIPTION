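Package: dimorphESS
Title: Eco-Evolutionary Dynamics of Sex-Specific Immune Defence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive-dynamics analysis of sex-specific investment in immune
    defence in a diploid, sexually reproducing host coupled to
    susceptible-infected-susceptible (SIS) pathogen dynamics. Two autosomal
    loci with sex-limited expression determine female and male defence
    traits, which are mapped to phenotypes (recovery rate, background
    mortality, fecundity during infection) through configurable life-history
    trade-offs. The package computes ecological equilibria, invasion fitness
    of rare mutant alleles as the dominant eigenvalue of the linearised
    mutant subsystem, pairwise-invasion plots, and evolutionarily stable
    strategies (ESSs) of the two sex-specific traits, together with sweeps
    of the ESS over sex-specific infection rates and virulences and a
    brute-force nonlinear simulation oracle for validating the eigenvalue
    criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
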
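Package: hybridzone
Title: Hybrid-Zone Analysis of Codominant Multiallelic Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of hybrid zones between diverged ecotypes genotyped at
    codominant multiallelic markers (microsatellites). Provides pedigree-defined
    genotypic classes (parentals, F1-F4, backcrosses B1-B8) with exact per-locus
    ancestry profiles, a Bayesian MCMC classifier assigning individuals posterior
    probabilities over genotypic classes, maximum-likelihood hybrid index and
    interecotypic heterozygosity with triangle diagnostics, per-population
    diversity statistics with permutation tests and a null-allele check,
    hierarchical AMOVA and pairwise Weir-Cockerham F-statistics, Nei standard
    genetic distance with neighbor-joining trees and locus bootstrap, simple and
    partial Mantel tests for isolation by distance and by environment, a
    Mendelian gene-dropping simulator of parental and hybrid cohorts, and an
    evaluation harness scoring classifier output against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    geosphere,
    MASS,
    graphics,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
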
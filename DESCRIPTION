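Package: grnevo
Title: Evolutionary Simulation of Hierarchical Developmental Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of populations of hierarchical developmental
    gene regulatory networks under environmental change. Each individual's genome
    is a set of six sparse interaction matrices; development is a recursive
    dynamical system that integrates (optionally) an environmental cue into an
    adult phenotype via layers of epigenetic marks, gene expression and
    higher-order complexes, with convergence judged by an exponential moving
    variance of the expressed phenotype. A genetic algorithm with
    roulette-wheel selection, row-block recombination and density-preserving
    mutation evolves the population over epochs of constant selective
    environment. Analysis tools include genotype and phenotype projections onto
    environment- and evolution-defined axes, mismatch, population genetic
    variance, phenotype-cue and phenotype-genome cross-covariance matrices and
    their singular value decomposition, developmental-bias proportion and
    alignment statistics, and a sweep over magnitudes of environmental change
    used to locate the transition between mutation-led and plasticity-led
    adaptation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'genome.R'
    'analysis.R'
    'development.R'
    'config.R'
    'environment.R'
    'fitness.R'
    'evolution.R'
    'grnevo-package.R'
    'sweep.R'
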
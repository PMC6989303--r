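Package: primsoc
Title: Phylogenetic Comparative Analysis of Primate Social Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the macroevolution of discrete social
    organization states (solitary, pair-living, unimale, multimale) on dated
    phylogenies. Implements constrained continuous-time Markov (Mk) models of
    trait evolution with a catalog of biologically motivated transition
    structures, maximum-likelihood and Bayesian (MCMC) fitting, reversible-jump
    search over rate-class partitions, stepping-stone estimation of marginal
    likelihoods with log Bayes factor comparison, marginal ancestral state
    reconstruction and stochastic character mapping with transition-count
    summaries, phylogenetic signal statistics (Blomberg's K, Pagel's lambda for
    discrete characters, the Fritz-Purvis D statistic), a taxon-subsampling
    robustness experiment, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    picante,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
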
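Package: gsbench
Title: Genomic Selection Benchmarking with Bayesian Whole-Genome Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and comparison of genomic prediction methods on
    QTLMAS-workshop-style pedigreed populations. Provides a pedigree, genome
    and trait simulator (gene dropping with Haldane recombination, imprinted
    and epistatic QTL), pedigree and genomic BLUP with restricted maximum
    likelihood variance estimation, Gibbs samplers for Bayesian whole-genome
    regression under Laplace (Bayesian LASSO), scaled Student-t (Bayes A) and
    spike-and-slab (Bayes B with normal or t slab) priors with their
    hyperparameters estimated from data, accuracy and variance-explained
    evaluation against true breeding values, and a GRAMMAR polygenic-adjusted
    single-SNP association scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
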
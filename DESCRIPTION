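Package: symbiodep
Title: Phylogenetic Comparative Analysis of Host-Symbiont Dependence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how dependent hosts are on their bacterial
    symbionts from published symbiont-removal experiments. Standardizes host
    fitness changes to percentage fitness drops, builds phylogenetic
    relatedness (variance-covariance) matrices from Newick trees, and fits
    single- and multi-response Gaussian Bayesian phylogenetic mixed models by
    Gibbs sampling, with per-observation measurement-error variances,
    inverse-Wishart priors, and transmission-specific (level-partitioned)
    covariance matrices. Includes posterior summaries (kernel-density mode,
    highest posterior density intervals, pMCMC, between-level differences,
    phylogenetic heritability, trait correlations and their difference test),
    Gelman-Rubin and Geweke convergence diagnostics, a synthetic-data
    generator emulating the structure of comparative symbiosis data sets, and
    a config-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, knitr, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
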
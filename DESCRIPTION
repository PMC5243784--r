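Package: socioconv
Title: Morphological Convergence Analysis for Social Lineages on Phylogenies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-methods toolkit for testing whether lineages sharing a
    social behaviour have converged in morphology. Implements Bayesian ancestral
    state reconstruction of binary behaviours under the liability threshold
    model (single-site Metropolis MCMC), Stayton's C1-C4 convergence indices
    with Brownian-motion simulation nulls, the Wheatsheaf index with
    permutation nulls, phylogenetic two-group t-tests with simulation null
    distributions and Holm correction, and Pagel's likelihood-ratio test for
    correlated evolution of two binary characters. Ships a synthetic-data
    generator that emulates a swallow-like study system (Yule tree, correlated
    threshold liabilities, Brownian or convergent Ornstein-Uhlenbeck trait
    evolution, specimen-level measurements) so the full pipeline runs and is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
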
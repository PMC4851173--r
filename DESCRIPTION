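Package: recsup
Title: Hierarchical Bayesian Supertrees from Gene-Tree Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers a rooted species tree from posterior distributions of
    unrooted gene-family tree topologies under a hierarchical Bayesian
    supertree model.  Gene-tree/species-tree disagreement is penalized
    jointly through a multivariate exponential distribution over four
    measures: minimum duplications, losses and deep coalescences from the
    LCA-mapping reconciliation (each minimized over all gene-tree rootings)
    and the mulRF distance for multi-labeled gene trees.  Posterior sampling
    uses generalized multiple-try Metropolis updates with importance
    resampling of gene trees, an optional exchange step for the intractable
    normalization constant, and a simulated-annealing mode that reduces to
    gene-tree parsimony under a single cost.  The package also ships a
    three-tree simulator (coalescent or Yule species trees, birth-death
    locus trees, multispecies-coalescent gene trees with gamma rate
    multipliers), a nonparametric generator of gene-tree uncertainty,
    distance-matrix baselines (GLASS, STEAC, SD, MAC) and an evaluation
    harness for split-accuracy benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
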
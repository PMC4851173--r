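# Nonparametric gene-tree uncertainty: turns one true gene tree (with branch
# lengths) into a weighted distribution of distinct topologies via
# length-dependent NNI perturbation, emulating the spread of a Bayesian
# gene-tree posterior.

#' Sample uncertainty-generator parameters
#'
#' Draws the perturbation parameters from their design laws: dispersion term
#' `LT ~ Uniform(2, 5)`, location term `DT ~ Uniform(3, 6)`, tree-wise
#' perturbation probability `pT = 1.1 Beta(LT DT, DT)` (values above 1 mean
#' every draw is perturbed; capped at use time), branch term
#' `LB ~ Uniform(1, 5)` and maximum per-branch swap probability
#' `pB = 1.5 Beta(LB, 1)`.
#'
#' @param n_draws number of perturbed draws per tree.
#' @param max_distinct maximum number of distinct topologies kept (default
#'   160).
#' @return object of class `uncertainty_params`.
#' @export
sample_uncertainty_params <- function(n_draws = 1000L, max_distinct = 160L) {
  LT <- stats::runif(1, 2, 5)
  DT <- stats::runif(1, 3, 6)
  pT <- 1.1 * stats::rbeta(1, LT * DT, DT)
  LB <- stats::runif(1, 1, 5)
  pB <- 1.5 * stats::rbeta(1, LB, 1)
  uncertainty_params(pT = pT, pB = pB, LT = LT, DT = DT, LB = LB,
                     n_draws = n_draws, max_distinct = max_distinct)
}

#' Uncertainty-generator parameters
#'
#' @param pT probability that a drawn tree is perturbed (may exceed 1 before
#'   capping).
#' @param pB maximum per-branch swap probability (may exceed 1; each internal
#'   branch `e` swaps with probability `min(1, pB * l_min / l_e)`, where
#'   `l_min` is the shortest internal branch, so short branches are the most
#'   uncertain).
#' @param LT,DT,LB shape terms kept for provenance.
#' @param n_draws,max_distinct see [sample_uncertainty_params()].
#' @export
uncertainty_params <- function(pT, pB, LT = NA, DT = NA, LB = NA,
                               n_draws = 1000L, max_distinct = 160L) {
  if (max_distinct < 1L) stop("max_distinct must be at least 1")
  structure(list(pT = pT, pB = pB, LT = LT, DT = DT, LB = LB,
                 n_draws = as.integer(n_draws),
                 max_distinct = as.integer(max_distinct)),
            class = "uncertainty_params")
}

#' Perturb a true gene tree into a weighted topology distribution
#'
#' Each of `n_draws` draws is either the true topology (probability
#' `1 - min(pT, 1)`) or a perturbed copy in which every internal branch `e`
#' is independently replaced by one of its two NNI alternatives with
#' probability `min(1, pB * l_min / l_e)`.  Distinct topologies are collected
#' with their frequencies as weights, truncated to the `max_distinct` most
#' frequent, and the true topology is force-included with at least one count
#' (disable with `force_true = FALSE`).
#'
#' @param true_tree binary `phylo` with positive branch lengths.
#' @param family the [gene_family()] the tree belongs to.
#' @param params an [uncertainty_params()].
#' @param force_true guarantee the true topology stays in the support.
#' @return a [gene_tree_distribution()].
#' @export
perturb_distribution <- function(true_tree, family, params, force_true = TRUE) {
  if (!ape::is.binary(true_tree)) stop("true tree must be binary")
  if (ape::Ntip(true_tree) < 4L)  # a single unrooted topology exists
    return(gene_tree_distribution(family, true_tree))
  ut <- phylo_to_utree(true_tree)
  m <- length(ut$leaves)
  if (is.null(ut$lengths)) stop("true tree must have branch lengths")
  res <- cpp_perturb_draws(ut$edges, ut$lengths, m, params$pT, params$pB,
                           params$n_draws)
  counts <- res$counts
  is_true <- res$is_true
  ord <- order(-counts)
  keep <- ord[seq_len(min(length(ord), params$max_distinct))]
  if (force_true && !any(is_true[keep])) {
    keep[length(keep)] <- which(is_true)
  }
  counts <- counts[keep]
  if (force_true) counts[is_true[keep]] <- pmax(counts[is_true[keep]], 1L)
  trees <- lapply(res$edges[keep], utree_to_phylo, labels = ut$leaves)
  gene_tree_distribution(family, trees, counts / sum(counts),
                         assume_distinct = TRUE)
}

#' Perturb every family of a simulated replicate
#'
#' Applies [perturb_distribution()] to each true (substitution-unit) gene
#' tree of a [sim_replicate()], with a single set of sampled uncertainty
#' parameters for the replicate.
#'
#' @param rep a [sim_replicate()].
#' @param params optional [uncertainty_params()]; sampled if missing.
#' @param n_draws,max_distinct forwarded to [sample_uncertainty_params()].
#' @return list of [gene_tree_distribution()] objects, with the used
#'   parameters as attribute `uncertainty_params`.
#' @export
perturb_replicate <- function(rep, params = NULL, n_draws = 1000L,
                              max_distinct = 160L) {
  if (is.null(params))
    params <- sample_uncertainty_params(n_draws = n_draws,
                                        max_distinct = max_distinct)
  out <- lapply(rep$families, function(f)
    perturb_distribution(f$gene_tree_subst, f$family, params))
  attr(out, "uncertainty_params") <- params
  out
}
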
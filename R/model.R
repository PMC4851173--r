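# The hierarchical probability model: unscaled multivariate exponential
# distance density, exponential hyperpriors on the penalties, uniform
# species-tree prior, joint unnormalized log posterior, and a brute-force
# partition function for small families.

#' Unscaled log density of a distance vector
#'
#' The core penalty term of the model: `-sum_j d_j / (m_j * lambda_j)`.
#' Exponentiated, this is the unnormalized probability of observing a gene
#' tree at distance vector `d` from the species tree.
#'
#' @param d numeric distance vector.
#' @param lambda strictly positive penalty parameters, one per distance.
#' @param m strictly positive scaling constants, one per distance.
#' @export
unscaled_log_density <- function(d, lambda, m) {
  if (length(d) != length(lambda) || length(d) != length(m))
    stop("d, lambda and m must have the same length")
  if (any(lambda <= 0) || any(m <= 0)) stop("lambda and m must be positive")
  -sum(d / (m * lambda))
}

#' Log exponential hyperprior for a penalty parameter
#'
#' `log P(lambda_ij | lambda_0j)` where the prior is exponential with mean
#' `lambda0j`.
#'
#' @param lambda_ij positive penalty value.
#' @param lambda0j positive prior mean.
#' @export
log_prior_lambda <- function(lambda_ij, lambda0j) {
  if (any(lambda_ij <= 0) || any(lambda0j <= 0)) stop("inputs must be positive")
  -lambda_ij / lambda0j - log(lambda0j)
}

#' Log hyper-hyperprior for the shared penalty scale
#'
#' `lambda_0j` follows an exponential distribution with fixed mean
#' `hyper_mean`.
#'
#' @param lambda0j positive value.
#' @param hyper_mean positive fixed mean (default 1).
#' @export
log_prior_lambda0 <- function(lambda0j, hyper_mean = 1) {
  if (any(lambda0j <= 0) || any(hyper_mean <= 0)) stop("inputs must be positive")
  -lambda0j / hyper_mean - log(hyper_mean)
}

#' Log uniform prior over rooted species-tree topologies
#'
#' There are `(2n - 3)!!` rooted binary labeled topologies on `n` species, so
#' the uniform prior assigns each `1 / (2n-3)!!`.
#'
#' @param n_species integer, at least 3.
#' @export
log_species_prior <- function(n_species) {
  if (n_species < 3) stop("need at least 3 species")
  -sum(log(seq(3, 2 * n_species - 3, by = 2)))
}

#' Unnormalized log joint posterior of a chain state
#'
#' Sums the unscaled distance densities over families, the penalty
#' hyperpriors, the shared-scale hyper-hyperpriors and the uniform
#' species-tree prior.  The phylogenetic likelihood term is represented by
#' the input resampling weights `log g_i(G_i)` (it cancels in all sampler
#' ratios but keeps reported posteriors comparable across gene-tree choices);
#' the partition function is neglected unless the exchange sampler is used.
#'
#' @param species_tree rooted `phylo` on all species.
#' @param dists list of [gene_tree_distribution()] objects.
#' @param gene_index integer vector: current topology index per family.
#' @param lambda numeric matrix, families by distances.
#' @param lambda0 numeric vector, one per distance.
#' @param m list of scaling-constant vectors, one per family (see
#'   [scaling_constants()]).
#' @param hyper_mean fixed mean of the hyper-hyperprior.
#' @param model `"DLIR"` or `"DLI"`.
#' @export
log_joint <- function(species_tree, dists, gene_index, lambda, lambda0, m,
                      hyper_mean = 1, model = "DLIR") {
  N <- length(dists)
  stopifnot(length(gene_index) == N, nrow(lambda) == N, length(m) == N)
  idx <- model_dist_idx(model)
  lp <- log_species_prior(ape::Ntip(species_tree))
  lp <- lp + sum(vapply(seq_along(lambda0), function(j)
    log_prior_lambda0(lambda0[j], hyper_mean), 0))
  for (i in seq_len(N)) {
    di <- dists[[i]]
    g <- gene_index[i]
    dv <- distance_vector(di$trees[[g]], species_tree, di$family$leaf_species,
                          model = if (3L %in% idx) "DLIR" else "DLI")
    dsel <- as.numeric(dv)[idx + 1L]
    lp <- lp + log(di$weights[g]) +
      unscaled_log_density(dsel, lambda[i, ], m[[i]]) +
      sum(vapply(seq_len(ncol(lambda)), function(j)
        log_prior_lambda(lambda[i, j], lambda0[j]), 0))
  }
  lp
}

#' Brute-force partition function of the distance distribution
#'
#' Sums `exp(unscaled_log_density)` over every unrooted binary topology on
#' the family's leaves against a fixed species tree.  Feasible only for
#' small families (`(2n-5)!!` topologies); the exchange sampler handles the
#' general case without ever computing this constant.
#'
#' @param family a [gene_family()].
#' @param species_tree rooted `phylo`.
#' @param lambda positive penalties, one per distance of `model`.
#' @param m scaling constants, one per distance of `model`.
#' @param model `"DLIR"`, `"DLI"`, `"DL"` or `"ILS"`.
#' @param max_leaves enumeration guard (default 8).
#' @return the normalization constant `Z` (a positive number).
#' @export
partition_function_bruteforce <- function(family, species_tree, lambda, m,
                                          model = "DLIR", max_leaves = 8L) {
  nl <- length(family$leaves)
  if (nl > max_leaves)
    stop("family too large for enumeration (", nl,
         " leaves); use the exchange sampler instead")
  idx <- model_dist_idx(model)
  stopifnot(length(lambda) == length(idx), length(m) == length(idx))
  topos <- all_topologies(family$leaves, rooted = FALSE, max_leaves = max_leaves)
  z <- 0
  for (t in topos) {
    dv <- distance_vector(t, species_tree, family$leaf_species,
                          model = if (3L %in% idx) "DLIR" else "DLI")
    d <- as.numeric(dv)[idx + 1L]
    z <- z + exp(unscaled_log_density(d, lambda, m))
  }
  z
}
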
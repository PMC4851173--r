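# Posterior sampling: generalized multiple-try Metropolis over the species
# tree, importance-resampled gene trees and penalty parameters, with optional
# exchange updates for the partition function and a simulated-annealing mode.

#' Sampler configuration
#'
#' @param iterations number of sweeps (one sweep updates the species tree,
#'   every family's gene tree, every family's penalty block, and the shared
#'   penalty scale).
#' @param burn_in fraction of sweeps discarded, in `[0, 1)`.
#' @param thin record every `thin`-th post-burn-in sweep; default keeps about
#'   1000 samples.
#' @param k_tries number of multiple-try candidates per update (at least 2).
#' @param seed optional integer seed applied at the start of the run.
#' @param mix proposal mix weights for the species-tree kernel
#'   `(nni, spr, reroot)`; all three kernels are symmetric.
#' @param exchange enable the exchange correction for the partition function.
#' @param aux_len auxiliary-chain length (sweeps) per exchange update.
#' @param anneal run as simulated annealing (geometric temperature schedule).
#' @param pre_anneal burn-in initialization temperature: the burn-in phase
#'   cools geometrically from this temperature down to `pre_floor` before
#'   exact sampling (at temperature 1) starts; `pre_anneal = 1` disables.
#'   This annealed initialization drives the chain into the high-posterior
#'   region regardless of the random start; recorded samples are always
#'   drawn at temperature 1.
#' @param pre_floor final burn-in temperature (may be below 1: the burn-in
#'   then ends with a short optimization, which the sampling phase relaxes).
#' @param kT_start,kT_end annealing temperature schedule endpoints.
#' @param sigma_lambda,sigma_lambda0 log-normal step sizes of the
#'   multiplicative penalty proposals.
#' @param update_species,update_genes,update_lambda,update_lambda0 toggles
#'   for individual update blocks (used by diagnostics and the single-block
#'   update helpers).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(iterations = 2000L, burn_in = 0.5, thin = NULL,
                           k_tries = 4L, seed = NULL,
                           mix = c(nni = 0.6, spr = 0.2, reroot = 0.2),
                           exchange = FALSE, aux_len = 100L, anneal = FALSE,
                           pre_anneal = 3.0, pre_floor = 0.2,
                           kT_start = 1.0, kT_end = 1e-3,
                           sigma_lambda = 0.5, sigma_lambda0 = 0.5,
                           update_species = TRUE, update_genes = TRUE,
                           update_lambda = TRUE, update_lambda0 = TRUE) {
  if (k_tries < 2L) stop("k_tries must be at least 2")
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)")
  if (kT_end > kT_start) stop("kT_end must not exceed kT_start")
  if (is.null(thin))
    thin <- max(1L, floor(iterations * (1 - burn_in) / 1000))
  structure(list(iterations = as.integer(iterations), burn_in = burn_in,
                 thin = as.integer(thin), k_tries = as.integer(k_tries),
                 seed = seed, mix = unname(mix), exchange = exchange,
                 aux_len = as.integer(aux_len), anneal = anneal,
                 pre_anneal = pre_anneal, pre_floor = pre_floor,
                 kT_start = kT_start, kT_end = kT_end,
                 sigma_lambda = sigma_lambda, sigma_lambda0 = sigma_lambda0,
                 update_species = update_species, update_genes = update_genes,
                 update_lambda = update_lambda, update_lambda0 = update_lambda0),
            class = "sampler_config")
}

cfg_to_cpp <- function(config, iterations = NULL, burn_in = NULL, thin = NULL,
                       gene_only = -1L) {
  list(iterations = if (is.null(iterations)) config$iterations else as.integer(iterations),
       k_tries = config$k_tries,
       thin = if (is.null(thin)) config$thin else as.integer(thin),
       burn_in = if (is.null(burn_in)) config$burn_in else burn_in,
       mix = as.numeric(config$mix), exchange = config$exchange,
       aux_len = config$aux_len, anneal = config$anneal,
       pre_anneal = if (is.null(config$pre_anneal)) 1.0 else config$pre_anneal,
       pre_floor = if (is.null(config$pre_floor)) 1.0 else config$pre_floor,
       kT_start = config$kT_start, kT_end = config$kT_end,
       sigma_lambda = config$sigma_lambda, sigma_lambda0 = config$sigma_lambda0,
       update_species = config$update_species, update_genes = config$update_genes,
       update_lambda = config$update_lambda, update_lambda0 = config$update_lambda0,
       gene_family_only = as.integer(gene_only))
}

#' Propose a new species tree
#'
#' One draw from the species-tree proposal kernel: nearest-neighbor
#' interchange, restricted subtree-prune-regraft, or rerooting (which leaves
#' the unrooted topology unchanged).  All three kernels are symmetric, so
#' no Hastings correction is needed.
#'
#' @param species_tree rooted binary `phylo`.
#' @param move `"nni"`, `"spr"`, `"reroot"`, or `NULL` to draw from `mix`.
#' @param mix kernel mix weights used when `move` is `NULL`.
#' @return list with the proposed `tree` and the logical `symmetric` flag
#'   (always `TRUE` for the implemented kernels).
#' @export
propose_species_tree <- function(species_tree, move = NULL,
                                 mix = c(nni = 0.6, spr = 0.2, reroot = 0.2)) {
  sp <- sort(species_tree$tip.label)
  par <- phylo_to_parent(species_tree, sp)
  if (is.null(move)) {
    move <- sample(c("nni", "spr", "reroot"), 1L, prob = unname(mix))
  }
  move <- match.arg(move, c("nni", "spr", "reroot"))
  newpar <- cpp_propose_species(par, move)
  list(tree = parent_to_phylo(newpar, sp), move = move, symmetric = TRUE)
}

# marshal one gene_tree_distribution into the kernel's family structure
family_to_cpp <- function(dist, species, m) {
  fam <- dist$family
  sp_ids <- sort(match(fam$species, species)) - 1L
  if (anyNA(sp_ids)) stop("family ", fam$id, " has species outside the species list")
  local_of_global <- integer(length(species))
  local_of_global[sp_ids + 1L] <- seq_along(sp_ids) - 1L
  leaf_local <- local_of_global[match(unname(fam$leaf_species[fam$leaves]), species)]
  edges <- lapply(dist$trees, function(t) phylo_to_utree(t, fam$leaves)$edges)
  list(nl = length(fam$leaves), species = as.integer(sp_ids),
       spp = as.integer(leaf_local), edges = edges,
       weights = as.numeric(dist$weights), m = as.numeric(m))
}

#' Build a chain state
#'
#' Assembles the full sampler state: species tree, per-family gene-tree
#' choice, penalty matrix and shared scales, plus the fixed scaling
#' constants.  Used by [run_chain()] and by the single-block update helpers
#' [gmtm_update()], [resample_gene_tree()] and [exchange_update()].
#'
#' @param dists list of [gene_tree_distribution()] objects.
#' @param species character vector of all species names.
#' @param model `"DLIR"`, `"DLI"`, `"DL"` or `"ILS"`.
#' @param init_tree optional rooted starting species tree (default random).
#' @param lambda_init optional penalty matrix (families x distances);
#'   default: independent draws from the hyperprior.
#' @param lambda0_init optional shared scales (default `hyper_mean`).
#' @param m optional list of per-family scaling constants; by default
#'   computed by [scaling_constants()] against `n_reference` random
#'   reference trees; use `m = 1` to force unit scales (gene-tree parsimony).
#' @param hyper_mean fixed mean of the exponential hyper-hyperprior on the
#'   shared penalty scales.  The hierarchy is deliberately informative toward
#'   small penalties (strong agreement): the default keeps the prior scale
#'   well below the per-distance resolution of the standardized distances so
#'   that the posterior over species trees concentrates rather than being
#'   dominated by the entropy of tree space; see the methods vignette.
#' @param n_reference number of random reference trees for the scales.
#' @return object of class `chain_state`.
#' @export
chain_state <- function(dists, species, model = "DLIR", init_tree = NULL,
                        lambda_init = NULL, lambda0_init = NULL, m = NULL,
                        hyper_mean = 3e-4, n_reference = 5L) {
  idx <- model_dist_idx(model)
  J <- length(idx)
  N <- length(dists)
  if (!N) stop("no gene families")
  species <- sort(species)
  if (is.null(init_tree)) init_tree <- random_species_tree(species)
  if (is.null(m)) {
    refs <- c(list(init_tree),
              lapply(seq_len(n_reference), function(i) random_species_tree(species)))
    m <- lapply(dists, scaling_constants, reference_trees = refs, model = model)
  } else if (is.numeric(m) && length(m) == 1L) {
    m <- lapply(seq_len(N), function(i) rep(m, J))
  }
  if (is.null(lambda0_init)) lambda0_init <- rep(hyper_mean, J)
  if (is.null(lambda_init))
    lambda_init <- matrix(stats::rexp(N * J, rate = 1 / rep(lambda0_init, each = N)),
                          nrow = N, ncol = J)
  gidx <- vapply(dists, function(d) which.max(d$weights), 0L)
  structure(list(dists = dists, species = species, model = model, idx = idx,
                 J = J, N = N,
                 species_parent = phylo_to_parent(init_tree, species),
                 gene_index = gidx, lambda = lambda_init,
                 lambda0 = lambda0_init, m = m, hyper_mean = hyper_mean,
                 fam_cpp = lapply(seq_len(N), function(i)
                   family_to_cpp(dists[[i]], species, m[[i]]))),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat("chain_state:", x$N, "families,", length(x$species), "species, model",
      x$model, "\n")
  invisible(x)
}

state_run <- function(state, config, iterations, gene_only = -1L) {
  cpp_run_chain(state$species_parent, length(state$species), state$fam_cpp,
                state$lambda, state$lambda0, state$gene_index - 1L,
                as.integer(state$idx), state$hyper_mean,
                cfg_to_cpp(config, iterations = iterations, burn_in = 0,
                           thin = 1L, gene_only = gene_only))
}

state_absorb <- function(state, res) {
  n <- nrow(res$species_parent)
  state$species_parent <- res$species_parent[n, ]
  state$gene_index <- res$gene_index[n, ] + 1L
  state$lambda <- matrix(res$lambda[n, ], nrow = state$N, byrow = TRUE)
  state$lambda0 <- res$lambda0[n, ]
  state$log_posterior <- res$log_posterior[n]
  state
}

#' Single multiple-try Metropolis block update
#'
#' Applies one GMTM update of the chosen block to a [chain_state()] and
#' returns the new state.  Candidate weights are the unnormalized posterior
#' (the unscaled joint distance density when the exchange correction is
#' active), and acceptance follows the generalized multiple-try ratio, so
#' detailed balance holds with respect to the unnormalized target.
#'
#' @param state a [chain_state()].
#' @param block one of `"species_tree"`, `"gene_trees"`, `"lambda"`,
#'   `"lambda0"`.
#' @param config a [sampler_config()]; its `k_tries`, step sizes and
#'   `exchange` flag are honored.
#' @return the updated `chain_state`.
#' @export
gmtm_update <- function(state, block = c("species_tree", "gene_trees",
                                         "lambda", "lambda0"),
                        config = sampler_config()) {
  block <- match.arg(block)
  cfg <- config
  cfg$update_species <- block == "species_tree"
  cfg$update_genes <- block == "gene_trees"
  cfg$update_lambda <- block == "lambda"
  cfg$update_lambda0 <- block == "lambda0"
  cfg$anneal <- FALSE
  state_absorb(state, state_run(state, cfg, iterations = 1L))
}

#' Importance resampling update of one family's gene tree
#'
#' Draws multiple-try candidates from the family's input weights, so the
#' phylogenetic-likelihood terms cancel and acceptance depends only on the
#' distance model.  The posterior support is therefore contained in the
#' input support.
#'
#' @param state a [chain_state()].
#' @param family_i family index (1-based); `NULL` updates all families.
#' @param config a [sampler_config()].
#' @return the updated `chain_state`.
#' @export
resample_gene_tree <- function(state, family_i = NULL, config = sampler_config()) {
  cfg <- config
  cfg$update_species <- FALSE; cfg$update_lambda <- FALSE
  cfg$update_lambda0 <- FALSE; cfg$update_genes <- TRUE; cfg$anneal <- FALSE
  gene_only <- if (is.null(family_i)) -1L else as.integer(family_i) - 1L
  state_absorb(state, state_run(state, cfg, iterations = 1L, gene_only = gene_only))
}

#' Exchange update of the species tree
#'
#' One species-tree GMTM update with the exchange correction: an auxiliary
#' gene tree per family is sampled from the model at the proposed state by a
#' secondary Markov chain over all topologies, and the acceptance ratio then
#' cancels the intractable partition functions.
#'
#' @param state a [chain_state()].
#' @param config a [sampler_config()]; `aux_len` controls the auxiliary
#'   chain length.
#' @return the updated `chain_state`.
#' @export
exchange_update <- function(state, config = sampler_config(exchange = TRUE)) {
  cfg <- config
  cfg$exchange <- TRUE
  gmtm_update(state, "species_tree", cfg)
}

#' Run the posterior sampler
#'
#' Runs the full Markov chain: each sweep updates the species tree, every
#' family's gene tree (by importance resampling from its input
#' distribution), every family's penalty block and the shared penalty
#' scales.  Returns the post-burn-in, thinned posterior sample.
#'
#' @inheritParams chain_state
#' @param config a [sampler_config()].
#' @param verbose print progress.
#' @return object of class `recsup_chain`: sampled rooted species trees
#'   (newick strings and `phylo` list), per-family gene-tree indices,
#'   penalty traces, unnormalized log posteriors, acceptance rates, and the
#'   inputs needed to summarize.
#' @export
run_chain <- function(dists, species, config = sampler_config(), model = "DLIR",
                      init_tree = NULL, lambda_init = NULL, lambda0_init = NULL,
                      m = NULL, hyper_mean = 3e-4, n_reference = 5L,
                      verbose = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- chain_state(dists, species, model = model, init_tree = init_tree,
                       lambda_init = lambda_init, lambda0_init = lambda0_init,
                       m = m, hyper_mean = hyper_mean, n_reference = n_reference)
  if (verbose)
    message("running ", config$iterations, " sweeps on ", state$N,
            " families / ", length(species), " species (", model, ")")
  res <- cpp_run_chain(state$species_parent, length(state$species),
                       state$fam_cpp, state$lambda, state$lambda0,
                       state$gene_index - 1L, as.integer(state$idx),
                       state$hyper_mean, cfg_to_cpp(config))
  trees <- apply(res$species_parent, 1L, function(p)
    ape::write.tree(parent_to_phylo(p, state$species)))
  structure(list(species_newick = trees,
                 species_parent = res$species_parent,
                 gene_index = res$gene_index + 1L,
                 lambda = res$lambda, lambda0 = res$lambda0,
                 log_posterior = res$log_posterior, iteration = res$iteration,
                 acceptance = res$acc, best = res$best, final = res$final,
                 state = state, config = config, model = model,
                 species = state$species, dists = dists, m = state$m),
            class = "recsup_chain")
}

#' @export
print.recsup_chain <- function(x, ...) {
  cat("recsup_chain:", length(x$species_newick), "samples,",
      length(x$species), "species,", x$state$N, "families, model", x$model, "\n")
  cat("acceptance:", paste(names(x$acceptance),
                           sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-likelihood species tree by simulated annealing
#'
#' Runs the sampler while geometrically cooling the target
#' `P(S, Theta | D)^(1/kT)` and returns the best state visited.  With a
#' single distance, fixed unit penalties and point-mass gene-tree inputs the
#' optimum coincides with the gene-tree-parsimony species tree for that
#' cost.
#'
#' @inheritParams run_chain
#' @param lambda_fixed optional fixed penalty value; disables penalty
#'   updates (unit scales via `m = 1` give plain total-cost parsimony).
#' @return list with `species_tree` (rooted `phylo`), `gene_index`,
#'   `lambda`, `lambda0`, `log_posterior`, and the full `chain` object.
#' @export
anneal <- function(dists, species, config = sampler_config(anneal = TRUE),
                   model = "DLIR", lambda_fixed = NULL, m = NULL,
                   hyper_mean = 3e-4, init_tree = NULL) {
  config$anneal <- TRUE
  idx <- model_dist_idx(model)
  lambda_init <- NULL
  if (!is.null(lambda_fixed)) {
    config$update_lambda <- FALSE
    config$update_lambda0 <- FALSE
    lambda_init <- matrix(lambda_fixed, nrow = length(dists), ncol = length(idx))
  }
  ch <- run_chain(dists, species, config = config, model = model,
                  init_tree = init_tree, lambda_init = lambda_init, m = m,
                  hyper_mean = hyper_mean)
  best <- ch$best
  list(species_tree = parent_to_phylo(best$species_parent, ch$species),
       gene_index = best$gene_index + 1L, lambda = best$lambda,
       lambda0 = best$lambda0, log_posterior = best$log_posterior,
       chain = ch)
}

entropy <- function(w) {
  w <- w[w > 0]
  -sum(w * log(w))
}

#' Summarize a posterior sample of species trees
#'
#' Computes the maximum a posteriori rooted topology (ties broken by higher
#' mean log posterior), the 50% majority-rule consensus (rooted and
#' unrooted), the 95% credible set of rooted topologies, a split support
#' table, and the per-family posterior gene-tree distributions.
#'
#' @param chain a `recsup_chain`.
#' @param level credible level (default 0.95).
#' @return object of class `recsup_summary`.
#' @export
summarize_posterior <- function(chain, level = 0.95) {
  nwk <- chain$species_newick
  if (!length(nwk)) stop("empty posterior sample")
  trees <- lapply(nwk, function(s) ape::read.tree(text = s))
  rkeys <- vapply(trees, rooted_key, "")
  tab <- sort(table(rkeys), decreasing = TRUE)
  freq <- as.numeric(tab) / length(rkeys)
  names(freq) <- names(tab)
  # MAP: most frequent; ties by mean log posterior
  top <- names(freq)[freq == freq[1]]
  if (length(top) > 1L) {
    mlp <- vapply(top, function(k) mean(chain$log_posterior[rkeys == k]), 0)
    map_key <- top[which.max(mlp)]
  } else map_key <- top
  map_tree <- trees[[match(map_key, rkeys)]]
  cons <- majority_consensus(trees, p = 0.5, rooted = TRUE)
  cons_unrooted <- majority_consensus(trees, p = 0.5, rooted = FALSE)
  cum <- cumsum(freq)
  ncred <- which(cum >= level)[1]
  if (is.na(ncred)) ncred <- length(freq)
  cred_keys <- names(freq)[seq_len(ncred)]
  cred_trees <- lapply(cred_keys, function(k) trees[[match(k, rkeys)]])
  support <- attr(cons_unrooted, "split_support")
  gene_post <- lapply(seq_len(chain$state$N), function(i) {
    idxs <- chain$gene_index[, i]
    counts <- tabulate(idxs, nbins = length(chain$dists[[i]]$trees))
    counts / sum(counts)
  })
  structure(list(map_tree = map_tree, map_key = map_key,
                 consensus = cons, consensus_unrooted = cons_unrooted,
                 credible_set = cred_trees, credible_keys = cred_keys,
                 credible_mass = cum[ncred],
                 topology_freq = freq, split_support = support,
                 gene_posterior = gene_post,
                 input_weights = lapply(chain$dists, `[[`, "weights")),
            class = "recsup_summary")
}

#' @export
print.recsup_summary <- function(x, ...) {
  cat("posterior summary:\n")
  cat("  MAP topology frequency:", sprintf("%.3f", x$topology_freq[1]), "\n")
  cat("  credible set size:", length(x$credible_set),
      sprintf("(mass %.3f)", x$credible_mass), "\n")
  cat("  consensus:", ape::write.tree(x$consensus), "\n")
  invisible(x)
}

#' Write a tab-separated sampler trace
#'
#' Columns: iteration, unnormalized log posterior, shared scales
#' `lambda0_j`, then per-family penalties `lambda_i_j`.  The format is
#' loadable by generic MCMC trace inspectors.
#'
#' @param chain a `recsup_chain`.
#' @param path output file.
#' @export
write_trace <- function(chain, path) {
  J <- chain$state$J
  N <- chain$state$N
  dn <- DIST_NAMES[chain$state$idx + 1L]
  df <- data.frame(iteration = chain$iteration,
                   log_posterior = chain$log_posterior)
  l0 <- as.data.frame(chain$lambda0)
  names(l0) <- paste0("lambda0_", dn)
  lam <- as.data.frame(chain$lambda)
  names(lam) <- as.vector(t(outer(seq_len(N), dn,
                                  function(i, d) paste0("lambda_", i, "_", d))))
  utils::write.table(cbind(df, l0, lam), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
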
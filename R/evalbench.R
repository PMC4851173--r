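# Evaluation harness: the performance measures (tree accuracy, true-tree
# recovery, credible-set coverage) and a scaled-down end-to-end replication
# of the simulation study.

#' Evaluate species-tree estimates against a replicate's truth
#'
#' Computes, per method, the unrooted split accuracy, whether the true
#' unrooted topology was perfectly recovered, and (for Bayesian estimates
#' with a credible set) whether the truth lies in the 95% credible set.
#'
#' @param true_tree the true species tree (`phylo`).
#' @param estimates named list of `phylo` estimates (may contain `NULL` for
#'   failed methods).
#' @param credible_sets optional named list (same names) of lists of `phylo`
#'   forming each method's credible set.
#' @param covariates optional single-row data.frame of replicate covariates
#'   to carry along.
#' @return data.frame with one row per method: `method`, `accuracy`,
#'   `recovered`, `covered` (NA when no credible set).
#' @export
evaluate_replicate <- function(true_tree, estimates, credible_sets = NULL,
                               covariates = NULL) {
  tkey <- topology_key(ape::unroot(true_tree))
  rows <- lapply(names(estimates), function(nm) {
    est <- estimates[[nm]]
    if (is.null(est))
      return(data.frame(method = nm, accuracy = NA_real_, recovered = NA,
                        covered = NA))
    acc <- split_accuracy(true_tree, est)
    rec <- identical(topology_key(ape::unroot(est)), tkey)
    cov <- NA
    if (!is.null(credible_sets) && nm %in% names(credible_sets)) {
      keys <- vapply(credible_sets[[nm]], function(t)
        topology_key(ape::unroot(t)), "")
      cov <- tkey %in% keys
    }
    data.frame(method = nm, accuracy = acc, recovered = rec, covered = cov)
  })
  out <- do.call(rbind, rows)
  if (!is.null(covariates)) out <- cbind(out, covariates, row.names = NULL)
  out
}

#' Benchmark configuration
#'
#' Scaled-down defaults of the simulation study sized for a single CPU:
#' 20 replicates with 8-15 species, 5-10 gene families and 1-3 individuals
#' per species, all other parameter laws unchanged, and 20,000 sampler
#' sweeps with 50% burn-in.
#'
#' @param n_replicates number of replicate data sets.
#' @param sim a [sim_params()] with the (restricted) parameter laws.
#' @param iterations,burn_in,k_tries sampler settings.
#' @param methods subset of `"bayes_dlir"`, `"bayes_dli"`, `"gtp_dl"`,
#'   `"gtp_ils"`, `"glass"`, `"steac"`, `"sd"`, `"mac"` (distance-matrix
#'   methods run both on true trees and on unit-length MAP input
#'   topologies).
#' @param n_draws,max_distinct uncertainty-generator settings.
#' @param anneal_iterations sweeps for the gene-tree-parsimony annealing
#'   runs.
#' @export
benchmark_config <- function(n_replicates = 20L,
                             sim = sim_params(n_species_range = c(8L, 15L),
                                              n_families_range = c(5L, 10L),
                                              individuals_range = c(1L, 3L)),
                             iterations = 20000L, burn_in = 0.5, k_tries = 4L,
                             methods = c("bayes_dlir", "gtp_dl", "gtp_ils",
                                         "glass", "steac", "sd", "mac"),
                             n_draws = 1000L, max_distinct = 160L,
                             anneal_iterations = 5000L) {
  structure(list(n_replicates = as.integer(n_replicates), sim = sim,
                 iterations = as.integer(iterations), burn_in = burn_in,
                 k_tries = as.integer(k_tries), methods = methods,
                 n_draws = as.integer(n_draws),
                 max_distinct = as.integer(max_distinct),
                 anneal_iterations = as.integer(anneal_iterations)),
            class = "benchmark_config")
}

#' Run the scaled-down simulation benchmark
#'
#' For each replicate: simulate the three-tree cascade, perturb the true
#' gene trees into weighted topology distributions, run the requested
#' inference methods, and score them against the true species tree.
#' Bayesian runs contribute a consensus and a MAP estimate plus 95%
#' coverage; the annealing runs are single-cost gene-tree-parsimony
#' estimates; distance-matrix methods run on the true gene trees
#' (`*_true`) and on the most frequent input topologies with unit branch
#' lengths (`*_topo`).
#'
#' @param config a [benchmark_config()].
#' @param seed integer seed; per-replicate seeds are derived from it and
#'   recorded in the output.
#' @param verbose print per-replicate progress.
#' @return data.frame of [evaluate_replicate()] rows with replicate
#'   covariates (species count, family count, coalescent tree length,
#'   expected duplications, individuals, smallest branch) and the
#'   per-replicate seed.
#' @export
run_benchmark <- function(config = benchmark_config(), seed = 1L,
                          verbose = FALSE) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, config$n_replicates)
  out <- list()
  for (r in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[r])
    rep <- sim_replicate(config$sim)
    dists <- perturb_replicate(rep, n_draws = config$n_draws,
                               max_distinct = config$max_distinct)
    truth <- rep$species_tree
    cov <- data.frame(
      replicate = r, seed = rep_seeds[r],
      n_species = rep$provenance$n_species,
      n_families = rep$provenance$n_families,
      tree_length_coal = rep$provenance$sigma_coal,
      edup = rep$provenance$edup,
      individuals = rep$provenance$individuals,
      min_branch_coal = min(rep$species_tree_coal$edge.length))
    estimates <- list(); credsets <- list()
    for (model in intersect(config$methods, c("bayes_dlir", "bayes_dli"))) {
      mod <- if (model == "bayes_dlir") "DLIR" else "DLI"
      ch <- run_chain(dists, rep$species,
                      config = sampler_config(iterations = config$iterations,
                                              burn_in = config$burn_in,
                                              k_tries = config$k_tries),
                      model = mod)
      sm <- summarize_posterior(ch)
      estimates[[paste0(model, "_cons")]] <- sm$consensus_unrooted
      estimates[[paste0(model, "_map")]] <- sm$map_tree
      credsets[[paste0(model, "_cons")]] <- sm$credible_set
      credsets[[paste0(model, "_map")]] <- sm$credible_set
    }
    for (gm in intersect(config$methods, c("gtp_dl", "gtp_ils"))) {
      mod <- if (gm == "gtp_dl") "DL" else "ILS"
      an <- anneal(dists, rep$species,
                   config = sampler_config(iterations = config$anneal_iterations,
                                           k_tries = config$k_tries,
                                           anneal = TRUE),
                   model = mod, lambda_fixed = 1, m = 1)
      estimates[[gm]] <- an$species_tree
    }
    dm <- intersect(config$methods, c("glass", "steac", "sd", "mac"))
    if (length(dm)) {
      true_trees <- lapply(rep$families, `[[`, "gene_tree_subst")
      maps <- lapply(rep$families, function(f) f$family$leaf_species)
      map_trees <- lapply(dists, function(d) d$trees[[which.max(d$weights)]])
      for (mm in dm) {
        M <- toupper(mm)
        estimates[[paste0(mm, "_true")]] <- tryCatch(
          run_distance_method(true_trees, maps, method = M, lengths = "true"),
          error = function(e) NULL)
        estimates[[paste0(mm, "_topo")]] <- tryCatch(
          run_distance_method(map_trees, maps, method = M, lengths = "unit"),
          error = function(e) NULL)
      }
    }
    out[[r]] <- evaluate_replicate(truth, estimates, credsets, covariates = cov)
    if (verbose)
      message(sprintf("replicate %d/%d: %s", r, config$n_replicates,
                      paste(sprintf("%s=%.2f", out[[r]]$method,
                                    out[[r]]$accuracy), collapse = " ")))
  }
  do.call(rbind, out)
}

#' Median accuracy per method from a benchmark table
#' @param results data.frame from [run_benchmark()].
#' @export
benchmark_summary <- function(results) {
  agg <- stats::aggregate(accuracy ~ method, data = results,
                          FUN = function(x) stats::median(x, na.rm = TRUE))
  rec <- stats::aggregate(recovered ~ method, data = results,
                          FUN = function(x) mean(x, na.rm = TRUE))
  merge(agg, rec, by = "method", all = TRUE)
}
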
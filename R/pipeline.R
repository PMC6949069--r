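#' Default pipeline configuration
#'
#' Tunable parameters of the full identification pipeline with their
#' defaults: differential-screen thresholds (FDR 0.05, |log2FC| > 1),
#' clique window [5, 8], Simpson merge cutoff 0.8, Pareto pruning, risk
#' alpha 0.05, and null sizes.
#'
#' @param fdr_max FDR threshold shared by both differential screens.
#' @param fc_min minimum |log2FC| for the DEG call.
#' @param n_null null draws for [devg_screen].
#' @param n_perm sign-flip permutations for [sam_deg].
#' @param min_size,max_size clique size window.
#' @param simpson Simpson merge threshold.
#' @param strategy pruning strategy, `"pareto"` or `"quantile"`.
#' @param quantile_q quantile for the quantile strategy.
#' @param dominance_tol tolerated dominating genes for Pareto pruning.
#' @param alpha risk-module significance level.
#' @param n_random random modules per candidate.
#' @param mi_role W penalty form, `"multiply"` or `"divide"`.
#' @param rng_seed integer seed driving every stochastic step.
#' @return named list of parameters.
#' @export
pipeline_config <- function(fdr_max = 0.05, fc_min = 1, n_null = 1000,
                            n_perm = 300, min_size = 5, max_size = 8,
                            simpson = 0.8, strategy = "pareto",
                            quantile_q = 0.5, dominance_tol = 4,
                            alpha = 0.05, n_random = 1000,
                            mi_role = "multiply", rng_seed = 1) {
  list(fdr_max = fdr_max, fc_min = fc_min, n_null = n_null,
       n_perm = n_perm, min_size = min_size, max_size = max_size,
       simpson = simpson, strategy = strategy, quantile_q = quantile_q,
       dominance_tol = dominance_tol, alpha = alpha, n_random = n_random,
       mi_role = mi_role, rng_seed = rng_seed)
}

#' Run the full risk-module identification pipeline
#'
#' Chains the four stages: differential screening (paired SAM-style DEGs
#' union variance-difference DEVGs), seed-anchored clique mining and
#' Simpson merging into primary modules, similarity pruning to candidate
#' modules, and triple-score permutation identification of risk modules.
#'
#' @param expr an [expression_matrix].
#' @param network an [interaction_network] (will be reduced to its
#'   seed-centered subgraph).
#' @param seeds character vector of seed genes.
#' @param annotations named list gene -> function ids.
#' @param config list from [pipeline_config].
#' @return list with `diff` (screen result), `seed_network`,
#'   `primary_modules`, `candidate_modules`, `reports`, `risk_modules`
#'   (the [gene_module]s called significant) and `risk_genes` (their gene
#'   union).
#' @export
run_pipeline <- function(expr, network, seeds, annotations,
                         config = pipeline_config()) {
  diff <- differential_screen(expr, fdr_max = config$fdr_max,
                              fc_min = config$fc_min,
                              n_null = config$n_null,
                              n_perm = config$n_perm,
                              rng_seed = config$rng_seed)
  seed_net <- extract_seed_network(network, seeds)
  cliques <- enumerate_cliques(seed_net, min_size = config$min_size,
                               max_size = config$max_size)
  cliques <- filter_cliques(cliques, seeds, diff$diff_genes)
  primary <- if (length(cliques) == 0) {
    list()
  } else {
    merge_cliques(cliques, seed_net, threshold = config$simpson)
  }
  mi <- mi_cache(expr, rng_seed = config$rng_seed)
  pruned <- lapply(primary, function(m) {
    obj <- suppressWarnings(gene_objectives(m, expr, mi = mi))
    prune_module(m, obj, strategy = config$strategy,
                 quantile_q = config$quantile_q,
                 dominance_tol = config$dominance_tol)
  })
  candidates <- select_candidates(pruned)
  reports <- if (length(candidates) == 0) {
    list()
  } else {
    identify_risk_modules(candidates, expr, annotations, seed_net,
                          alpha = config$alpha,
                          n_random = config$n_random,
                          rng_seed = config$rng_seed,
                          mi_role = config$mi_role)
  }
  risky <- vapply(reports, `[[`, logical(1), "is_risk")
  risk_modules <- candidates[risky]
  list(diff = diff, seed_network = seed_net, primary_modules = primary,
       candidate_modules = candidates, reports = reports,
       risk_modules = risk_modules,
       risk_genes = sort(unique(unlist(lapply(risk_modules,
                                              `[[`, "genes")))))
}

#' Stability of risk modules under sample resampling
#'
#' Reruns the full pipeline `reps` times on a random subset of
#' tumor/normal pairs (whole pairs are dropped so pairing is preserved)
#' and reports, per replicate, how many full-data risk-module genes are
#' re-identified.
#'
#' @param expr an [expression_matrix].
#' @param network an [interaction_network].
#' @param seeds seed genes.
#' @param annotations annotation map.
#' @param config list from [pipeline_config].
#' @param fraction fraction of pairs kept per replicate (default 0.9).
#' @param reps number of replicates (default 100).
#' @param rng_seed integer seed for the pair subsampling.
#' @return list with `full_genes` (risk genes on all samples),
#'   `replicates` (data.frame `rep`, `n_pairs`, `n_risk_genes`,
#'   `overlap`) and `full_result`.
#' @export
robustness_resample <- function(expr, network, seeds, annotations,
                                config = pipeline_config(),
                                fraction = 0.9, reps = 100,
                                rng_seed = 1) {
  if (fraction <= 0 || fraction > 1) {
    abort_riskmod("fraction must be in (0, 1]", "riskmod_config_error")
  }
  full <- run_pipeline(expr, network, seeds, annotations, config)
  full_genes <- full$risk_genes
  pair_ids <- unique(expr$samples$pair_id)
  n_keep <- max(1L, round(fraction * length(pair_ids)))
  subsets <- with_rng_seed(rng_seed, {
    lapply(seq_len(reps), function(i) sample(pair_ids, n_keep))
  })
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    keep <- expr$samples$pair_id %in% subsets[[i]]
    sub <- tryCatch(
      expression_matrix(expr$values[, keep, drop = FALSE],
                        expr$samples[keep, , drop = FALSE]),
      riskmod_error = function(e) NULL)
    if (is.null(sub)) {
      message(sprintf("replicate %d skipped: too few pairs", i))
      next
    }
    res <- run_pipeline(sub, network, seeds, annotations, config)
    rows[[i]] <- data.frame(rep = i, n_pairs = n_keep,
                            n_risk_genes = length(res$risk_genes),
                            overlap = length(intersect(res$risk_genes,
                                                       full_genes)))
  }
  list(full_genes = full_genes,
       replicates = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       full_result = full)
}
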
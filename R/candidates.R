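#' Per-gene similarity objectives against a module's seed genes
#'
#' For each non-seed gene y in the module, computes the two similarity
#' criteria that candidate selection maximizes jointly: `mi_sum`, the sum
#' over measured seed genes x of the (0-floored) KSG mutual information
#' MI(x, y), and `pcc_avg`, the mean absolute Pearson correlation with the
#' seeds. Both are computed over all pooled samples (tumor + normal).
#' Seeds or non-seeds without expression data are skipped with a warning.
#'
#' @param module a [gene_module].
#' @param expr an [expression_matrix].
#' @param k neighbor count for the MI estimator (default 3).
#' @param rng_seed seed for MI tie-breaking jitter.
#' @param mi mutual-information lookup `function(u, v)`; defaults to a
#'   fresh memoised KSG estimator over `expr` (supply a shared [mi_cache]
#'   to reuse estimates across modules).
#' @return data.frame with columns `gene`, `mi_sum`, `pcc_avg`.
#' @export
gene_objectives <- function(module, expr, k = 3, rng_seed = 0, mi = NULL) {
  measured <- rownames(expr$values)
  seeds <- intersect(module$seed_genes, measured)
  if (length(seeds) == 0) {
    abort_riskmod("no module seed gene has expression data",
                  "riskmod_config_error")
  }
  skipped <- setdiff(module$seed_genes, measured)
  if (length(skipped) > 0) {
    warning(sprintf("skipping %d unmeasured seed gene(s): %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  if (is.null(mi)) {
    mi <- mi_cache(expr, k = k, rng_seed = rng_seed)
  }
  ys <- intersect(module$nonseed_genes, measured)
  lost <- setdiff(module$nonseed_genes, measured)
  if (length(lost) > 0) {
    warning(sprintf("dropping %d unmeasured non-seed gene(s): %s",
                    length(lost), paste(lost, collapse = ", ")))
  }
  vals <- expr$values
  mi_sum <- numeric(length(ys))
  pcc_avg <- numeric(length(ys))
  for (i in seq_along(ys)) {
    y <- ys[i]
    mi_sum[i] <- sum(vapply(seeds, function(x) max(0, mi(x, y)),
                            numeric(1)))
    pcc_avg[i] <- mean(vapply(seeds, function(x) {
      abs(pearson_correlation(vals[x, ], vals[y, ]))
    }, numeric(1)))
  }
  data.frame(gene = ys, mi_sum = mi_sum, pcc_avg = pcc_avg,
             stringsAsFactors = FALSE)
}

# TRUE where gene i is strictly worse than some other retained gene in
# both objectives; returns the count of genes dominating each gene
dominance_counts <- function(mi_sum, pcc_avg) {
  n <- length(mi_sum)
  vapply(seq_len(n), function(i) {
    sum(mi_sum > mi_sum[i] & pcc_avg > pcc_avg[i])
  }, integer(1))
}

#' Prune a module to seed-similar non-seed genes
#'
#' Seeds are always retained. Under the default `pareto` strategy the
#' non-seed gene dominated by the most others (strictly worse in both
#' `mi_sum` and `pcc_avg`) is removed repeatedly until every retained
#' non-seed is dominated by at most `dominance_tol` retained genes, or
#' only one remains; `dominance_tol = 0` keeps exactly the strict Pareto
#' front, while the default 4 tolerates the few-dominator ties that arise
#' among genuinely equivalent co-expressed genes (a strict front among
#' exchangeable genes is small by construction, discarding genes as
#' similar to the seeds as the ones kept). Under `quantile`,
#' non-seeds at or above the module's `quantile_q` quantile in BOTH
#' objectives are retained. Induced edges are recomputed.
#'
#' @param module a [gene_module].
#' @param objectives data.frame from [gene_objectives].
#' @param strategy `"pareto"` (default) or `"quantile"`.
#' @param quantile_q quantile for the `quantile` strategy (default 0.5).
#' @param dominance_tol maximum tolerated number of dominating genes under
#'   the `pareto` strategy (default 4).
#' @return the pruned [gene_module] (label suffixed with `.cand`).
#' @export
prune_module <- function(module, objectives,
                         strategy = c("pareto", "quantile"),
                         quantile_q = 0.5, dominance_tol = 4) {
  strategy <- tryCatch(match.arg(strategy),
                       error = function(e) {
                         abort_riskmod("unknown pruning strategy",
                                       "riskmod_config_error")
                       })
  obj <- objectives[order(objectives$gene), , drop = FALSE]
  keep <- obj$gene
  if (strategy == "pareto") {
    while (length(keep) > 1) {
      idx <- match(keep, obj$gene)
      dom <- dominance_counts(obj$mi_sum[idx], obj$pcc_avg[idx])
      if (all(dom <= dominance_tol)) break
      worst <- keep[which(dom == max(dom))]
      keep <- setdiff(keep, sort(worst)[1])
    }
  } else {
    if (length(keep) > 0) {
      qmi <- quantile(obj$mi_sum, quantile_q, names = FALSE)
      qpc <- quantile(obj$pcc_avg, quantile_q, names = FALSE)
      keep <- obj$gene[obj$mi_sum >= qmi & obj$pcc_avg >= qpc]
    }
  }
  genes <- sort(c(module$seed_genes, keep))
  gene_module(genes, module$seed_genes,
              induced_edges(module$edges, genes),
              label = paste0(module$label, ".cand"))
}

#' Keep modules that still contain non-seed genes
#'
#' A pruned module reduced to seeds alone carries no new candidate
#' disease genes and is dropped.
#'
#' @param modules list of [gene_module] objects.
#' @return the modules with >= 1 non-seed gene, in input order.
#' @export
select_candidates <- function(modules) {
  Filter(function(m) length(m$nonseed_genes) >= 1, modules)
}
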
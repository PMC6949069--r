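#' Paired differential statistic of one gene
#'
#' Absolute paired t statistic of the within-pair tumor - normal
#' differences. When the differences have zero spread but nonzero mean the
#' statistic is infinite in theory; it is capped at `t_cap` with a
#' warning. All-zero differences return 0.
#'
#' @param expr an [expression_matrix].
#' @param gene gene symbol.
#' @param t_cap cap for the degenerate zero-spread case (default 100).
#' @return nonnegative scalar |t|.
#' @export
gene_diff_statistic <- function(expr, gene, t_cap = 100) {
  if (!gene %in% rownames(expr$values)) {
    abort_riskmod(sprintf("gene '%s' not in expression matrix", gene),
                  "riskmod_lookup_error")
  }
  z <- paired_differences(expr)[gene, ]
  if (length(z) < 3) {
    abort_riskmod("paired t needs at least 3 pairs",
                  "riskmod_insufficient_data_error")
  }
  if (sd(z) == 0) {
    if (mean(z) == 0) {
      return(0)
    }
    warning(sprintf("gene '%s': zero-variance differences, t capped", gene))
    return(t_cap)
  }
  abs(mean(z) / (sd(z) / sqrt(length(z))))
}

# |t| for every gene at once; degenerate rows get 0 (all-zero) or t_cap
diff_statistics <- function(expr, t_cap = 100) {
  z <- paired_differences(expr)
  P <- ncol(z)
  zbar <- rowMeans(z)
  s <- sqrt(rowSums((z - zbar)^2) / (P - 1))
  f <- abs(zbar / (s / sqrt(P)))
  f[s == 0 & zbar == 0] <- 0
  f[s == 0 & zbar != 0] <- t_cap
  f
}

#' Markov-random-field module score W
#'
#' `W = (1/m) * sum(f over seed genes C1) - (1/k) * sum over module edges
#' (u, v) with both endpoints non-seed of (f_u/d_u - f_v/d_v)^2 * MI(u, v)`,
#' where f is the per-gene absolute paired t statistic, m the number of
#' genes in the module, d the node degree in the module-defining network
#' and k the number of edges in the module.
#' The first term rewards differential seed genes; the second penalizes
#' discordant degree-normalized differential levels between strongly
#' dependent non-seed neighbors (an MRF smoothness energy). Negative MI
#' estimates are floored at 0. With `mi_role = "divide"` the penalty
#' divides by `max(MI, 1e-6)` instead.
#'
#' @param module a [gene_module].
#' @param f named numeric vector of per-gene differential statistics
#'   (from [diff_statistics] / [gene_diff_statistic]).
#' @param mi mutual-information lookup `function(u, v)` (see [mi_cache]).
#' @param network the module-defining [interaction_network] (source of
#'   degrees), or a named numeric vector of degrees.
#' @param mi_role `"multiply"` (default) or `"divide"`.
#' @return scalar W.
#' @export
mrf_module_score <- function(module, f, mi, network,
                             mi_role = c("multiply", "divide")) {
  mi_role <- match.arg(mi_role)
  k <- nrow(module$edges)
  m <- length(module$genes)
  if (length(module$seed_genes) == 0) {
    warning(sprintf("module '%s' has no seed gene; first term is 0",
                    module$label))
    first <- 0
  } else {
    first <- sum(f[module$seed_genes]) / m
  }
  if (k == 0) {
    warning(sprintf("module '%s' has no edges; penalty term is 0",
                    module$label))
    return(first)
  }
  deg <- if (is.numeric(network)) network else network_degrees(network)
  e <- module$edges
  both_nonseed <- e$from %in% module$nonseed_genes &
    e$to %in% module$nonseed_genes
  penalty <- 0
  for (idx in which(both_nonseed)) {
    u <- e$from[idx]
    v <- e$to[idx]
    m_uv <- max(0, mi(u, v))
    gap <- (f[[u]] / deg[[u]] - f[[v]] / deg[[v]])^2
    penalty <- penalty + if (mi_role == "multiply") {
      gap * m_uv
    } else {
      gap / max(m_uv, 1e-6)
    }
  }
  first - penalty / k
}

#' Functional-consistency score F
#'
#' Mean Jaccard index of annotation sets over all (seed, non-seed) gene
#' pairs of the module in which BOTH genes carry at least one annotation;
#' pairs with an unannotated member are excluded. Returns 0 when no pair
#' is eligible.
#'
#' @param module a [gene_module].
#' @param annotations named list gene -> character vector of function ids
#'   (see [annotation_map_from_sets]).
#' @return score in [0, 1].
#' @export
function_consistency <- function(module, annotations) {
  ann <- function(g) {
    a <- annotations[[g]]
    if (is.null(a)) character(0) else unique(a)
  }
  seeds <- Filter(function(g) length(ann(g)) > 0, module$seed_genes)
  nons <- Filter(function(g) length(ann(g)) > 0, module$nonseed_genes)
  if (length(seeds) == 0 || length(nons) == 0) {
    return(0)
  }
  jac <- outer(seeds, nons, Vectorize(function(x, y) {
    fx <- ann(x)
    fy <- ann(y)
    length(intersect(fx, fy)) / length(union(fx, fy))
  }))
  mean(jac)
}

#' Between-condition correlation difference of a module
#'
#' Sum over unordered measured gene pairs of
#' `|PCC_tumor(x, y) - PCC_normal(x, y)|` (or the signed difference when
#' `signed = TRUE`). Captures rewiring of co-expression between tumor and
#' normal states. Genes with zero variance in either condition are
#' excluded with a warning.
#'
#' @param module a [gene_module].
#' @param expr an [expression_matrix] with >= 3 samples per condition.
#' @param signed sum signed differences instead of absolute (default
#'   FALSE).
#' @return nonnegative scalar (when `signed = FALSE`).
#' @export
pcc_difference <- function(module, expr, signed = FALSE) {
  genes <- intersect(module$genes, rownames(expr$values))
  tum <- condition_matrix(expr, "tumor")
  nor <- condition_matrix(expr, "normal")
  if (ncol(tum) < 3 || ncol(nor) < 3) {
    abort_riskmod("need at least 3 samples per condition",
                  "riskmod_insufficient_data_error")
  }
  row_sd <- function(m) apply(m, 1, sd)
  ok <- genes[row_sd(tum[genes, , drop = FALSE]) > 0 &
                row_sd(nor[genes, , drop = FALSE]) > 0]
  if (length(ok) < length(genes)) {
    warning("excluding zero-variance gene(s) from PCC difference")
  }
  if (length(ok) < 2) {
    abort_riskmod("PCC difference needs >= 2 measured genes",
                  "riskmod_insufficient_data_error")
  }
  ct <- cor(t(tum[ok, , drop = FALSE]))
  cn <- cor(t(nor[ok, , drop = FALSE]))
  d <- ct - cn
  if (!signed) {
    d <- abs(d)
  }
  sum(d[upper.tri(d)])
}

#' Sample size-matched random modules
#'
#' Each random module draws `n_seeds` seed nodes and `n_genes - n_seeds`
#' non-seed nodes uniformly without replacement from the network, with
#' edges induced; this is the null model behind the permutation p-values.
#'
#' @param network an [interaction_network].
#' @param n_genes module size.
#' @param n_seeds number of seed genes per random module.
#' @param count number of modules (default 1000).
#' @param rng_seed integer seed; output is deterministic given it.
#' @return list of [gene_module] objects labeled `R1`, `R2`, ...
#' @export
random_modules <- function(network, n_genes, n_seeds, count = 1000,
                           rng_seed = 1) {
  seeds <- names(network$is_seed)[network$is_seed]
  nonseeds <- names(network$is_seed)[!network$is_seed]
  if (n_seeds > length(seeds) || (n_genes - n_seeds) > length(nonseeds) ||
      n_seeds < 0 || n_genes < n_seeds) {
    abort_riskmod("network too small for requested module composition",
                  "riskmod_sampling_error")
  }
  with_rng_seed(rng_seed, {
    lapply(seq_len(count), function(i) {
      genes <- c(sample(seeds, n_seeds),
                 sample(nonseeds, n_genes - n_seeds))
      gene_module(genes, seeds, induced_edges(network$edges, genes),
                  label = paste0("R", i))
    })
  })
}

#' Upper-tail permutation p-value
#'
#' `p = (1 + #(null >= observed)) / (length(null) + 1)`; the add-one
#' convention keeps p strictly positive.
#'
#' @param observed scalar observed score.
#' @param null_scores numeric vector of null scores.
#' @return p-value in (0, 1].
#' @export
permutation_p <- function(observed, null_scores) {
  if (length(null_scores) == 0) {
    abort_riskmod("null score vector is empty", "riskmod_input_error")
  }
  (1 + sum(null_scores >= observed)) / (length(null_scores) + 1)
}

#' Identify risk modules by triple permutation significance
#'
#' For each candidate module computes the MRF score W, the
#' functional-consistency score F and the correlation-difference score
#' dPCC, then compares each against `n_random` size-matched random modules
#' (same gene and seed counts, sampled from the measured subnetwork). A
#' candidate is a risk module when all three upper-tail permutation
#' p-values fall below `alpha`.
#'
#' @param candidates list of [gene_module] objects.
#' @param expr an [expression_matrix].
#' @param annotations named list gene -> function ids.
#' @param network the module-defining [interaction_network].
#' @param alpha significance level (default 0.05).
#' @param n_random null modules per candidate (default 1000).
#' @param rng_seed integer seed.
#' @param mi_role penalty form for W, see [mrf_module_score].
#' @return list of score reports (one per candidate, input order); each is
#'   a list with `label`, `W`, `F`, `dPCC`, `p_W`, `p_F`, `p_dPCC`,
#'   `null_W`, `null_F`, `null_dPCC`, `is_risk`.
#' @export
identify_risk_modules <- function(candidates, expr, annotations, network,
                                  alpha = 0.05, n_random = 1000,
                                  rng_seed = 1,
                                  mi_role = c("multiply", "divide")) {
  mi_role <- match.arg(mi_role)
  measured <- intersect(network$nodes, rownames(expr$values))
  subnet <- interaction_network(induced_edges(network$edges, measured),
                                seeds = names(network$is_seed)[network$is_seed])
  f <- diff_statistics(expr)
  mi <- mi_cache(expr)
  score_module <- function(m) {
    list(W = mrf_module_score(m, f, mi, subnet, mi_role = mi_role),
         F = function_consistency(m, annotations),
         dPCC = pcc_difference(m, expr))
  }
  reports <- vector("list", length(candidates))
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    obs <- score_module(cand)
    nulls <- random_modules(subnet, n_genes = length(cand$genes),
                            n_seeds = length(cand$seed_genes),
                            count = n_random,
                            rng_seed = rng_seed + ci)
    null_scores <- suppressWarnings(lapply(nulls, score_module))
    null_W <- vapply(null_scores, `[[`, numeric(1), "W")
    null_F <- vapply(null_scores, `[[`, numeric(1), "F")
    null_d <- vapply(null_scores, `[[`, numeric(1), "dPCC")
    p_W <- permutation_p(obs$W, null_W)
    p_F <- permutation_p(obs$F, null_F)
    p_d <- permutation_p(obs$dPCC, null_d)
    reports[[ci]] <- list(label = cand$label, W = obs$W, F = obs$F,
                          dPCC = obs$dPCC, p_W = p_W, p_F = p_F,
                          p_dPCC = p_d, null_W = null_W, null_F = null_F,
                          null_dPCC = null_d,
                          is_risk = p_W < alpha && p_F < alpha &&
                            p_d < alpha)
  }
  reports
}

#' Summarise risk-module score reports
#' @param reports list from [identify_risk_modules].
#' @return data.frame with one row per candidate module.
#' @export
risk_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(label = r$label, W = r$W, F = r$F, dPCC = r$dPCC,
               p_W = r$p_W, p_F = r$p_F, p_dPCC = r$p_dPCC,
               is_risk = r$is_risk, stringsAsFactors = FALSE)
  }))
}
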
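#' Sample variance of an expression vector
#'
#' Measures how far a gene's expression deviates from its average across
#' samples: `sum((x - mean(x))^2) / (N - 1)`.
#'
#' @param values numeric vector of length >= 2.
#' @return nonnegative scalar variance.
#' @export
gene_variance <- function(values) {
  if (length(values) < 2) {
    abort_riskmod("variance needs at least 2 values",
                  "riskmod_insufficient_data_error")
  }
  var(values)
}

#' Between-condition variance difference of one gene
#'
#' `V = |S2_normal - S2_tumor|`, the absolute difference of the gene's
#' sample variances in the two conditions. A large V marks a gene whose
#' expression variability (not necessarily its mean) changes with disease
#' state.
#'
#' @param expr an [expression_matrix].
#' @param gene gene symbol.
#' @return nonnegative scalar V.
#' @export
variance_difference <- function(expr, gene) {
  if (!gene %in% rownames(expr$values)) {
    abort_riskmod(sprintf("gene '%s' not in expression matrix", gene),
                  "riskmod_lookup_error")
  }
  tum <- condition_matrix(expr, "tumor")[gene, ]
  nor <- condition_matrix(expr, "normal")[gene, ]
  abs(gene_variance(nor) - gene_variance(tum))
}

# V for every gene at once (rows of the two condition submatrices)
variance_difference_all <- function(expr) {
  tum <- condition_matrix(expr, "tumor")
  nor <- condition_matrix(expr, "normal")
  row_var <- function(m) rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
  abs(row_var(nor) - row_var(tum))
}

#' Screen differential expression-variance genes (DEVGs)
#'
#' Tests each gene's variance difference V against a shared permutation
#' null: each of `n_null` draws picks a uniformly random gene, swaps its
#' tumor/normal values within a random subset of pairs (so the pairing
#' structure is respected), and records the resulting V. Per-gene empirical
#' p-values use the add-one convention `(1 + #(null >= V)) / (n_null + 1)`
#' and are BH-adjusted across genes.
#'
#' @param expr an [expression_matrix].
#' @param n_null size of the shared null sample (>= 100; default 1000).
#' @param fdr_max FDR threshold for the DEVG call (default 0.05).
#' @param rng_seed integer seed; the screen is deterministic given it.
#' @return data.frame with columns `gene`, `V`, `V_p`, `V_fdr`, `is_devg`.
#' @export
devg_screen <- function(expr, n_null = 1000, fdr_max = 0.05, rng_seed = 1) {
  if (n_null < 100) {
    abort_riskmod("n_null must be at least 100", "riskmod_config_error")
  }
  tum <- condition_matrix(expr, "tumor")
  nor <- condition_matrix(expr, "normal")
  genes <- rownames(expr$values)
  V <- variance_difference_all(expr)
  P <- ncol(tum)
  null_V <- with_rng_seed(rng_seed, {
    vapply(seq_len(n_null), function(b) {
      gi <- sample.int(length(genes), 1)
      sw <- runif(P) < 0.5
      t2 <- ifelse(sw, nor[gi, ], tum[gi, ])
      n2 <- ifelse(sw, tum[gi, ], nor[gi, ])
      abs(var(n2) - var(t2))
    }, numeric(1))
  })
  # count null >= V via the sorted null
  sorted <- sort(null_V)
  n_ge <- n_null - findInterval(V, sorted, left.open = TRUE)
  p <- (1 + n_ge) / (n_null + 1)
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene = genes, V = unname(V), V_p = unname(p),
             V_fdr = unname(fdr), is_devg = unname(fdr < fdr_max),
             stringsAsFactors = FALSE)
}

#' Screen differentially expressed genes (paired SAM-style test)
#'
#' Computes per-gene paired differences `z = tumor - normal`, the
#' moderated statistic `d = mean(z) / (se(z) + s0)` with `s0` the median of
#' all genes' standard errors (the fudge factor that stabilises low-variance
#' genes), and `log2fc = mean(z)` (data are log2 scale). The FDR is
#' estimated by sign-flip permutations of pairs: for each gene the median
#' permutation count of statistics at least as extreme as its observed |d|
#' is divided by the observed rank of |d|, clipped to [0,1] and made
#' monotone along decreasing |d|.
#'
#' @param expr an [expression_matrix].
#' @param fdr_max FDR threshold (default 0.05).
#' @param fc_min minimum |log2 fold change| (default 1).
#' @param n_perm number of sign-flip permutations (default 300).
#' @param rng_seed integer seed.
#' @return data.frame with columns `gene`, `sam_d`, `log2fc`, `sam_fdr`,
#'   `is_deg`.
#' @export
sam_deg <- function(expr, fdr_max = 0.05, fc_min = 1, n_perm = 300,
                    rng_seed = 1) {
  z <- paired_differences(expr)
  P <- ncol(z)
  if (P < 3) {
    abort_riskmod("paired SAM needs at least 3 pairs",
                  "riskmod_insufficient_data_error")
  }
  genes <- rownames(z)
  zbar <- rowMeans(z)
  se <- sqrt(rowSums((z - zbar)^2) / (P - 1) / P)
  s0 <- median(se)
  d <- zbar / (se + s0)
  absd <- abs(d)
  ord <- order(absd, decreasing = TRUE)
  rank_desc <- integer(length(d))
  rank_desc[ord] <- seq_along(d)
  counts <- with_rng_seed(rng_seed, {
    vapply(seq_len(n_perm), function(b) {
      signs <- sample(c(-1, 1), P, replace = TRUE)
      zp <- sweep(z, 2, signs, `*`)
      zpbar <- rowMeans(zp)
      sep <- sqrt(rowSums((zp - zpbar)^2) / (P - 1) / P)
      dp <- sort(abs(zpbar / (sep + s0)))
      # per gene: number of permuted |d| >= observed |d|
      length(dp) - findInterval(absd, dp, left.open = TRUE)
    }, numeric(length(d)))
  })
  med_false <- apply(counts, 1, median)
  q <- pmin(pmax(med_false / rank_desc, 0), 1)
  # q must not decrease as |d| gets smaller
  q[ord] <- cummax(q[ord])
  is_deg <- q < fdr_max & abs(zbar) > fc_min
  data.frame(gene = genes, sam_d = unname(d), log2fc = unname(zbar),
             sam_fdr = unname(q), is_deg = unname(is_deg),
             stringsAsFactors = FALSE)
}

#' Union of DEG and DEVG calls
#' @param deg character vector of DEG symbols.
#' @param devg character vector of DEVG symbols.
#' @return sorted union; these are the differential genes carried forward.
#' @export
differential_union <- function(deg, devg) {
  sort(union(deg, devg))
}

#' Run both differential screens and combine them
#'
#' @param expr an [expression_matrix].
#' @param fdr_max FDR threshold shared by both screens.
#' @param fc_min minimum |log2FC| for the DEG call.
#' @param n_null null size for [devg_screen].
#' @param n_perm permutations for [sam_deg].
#' @param rng_seed integer seed.
#' @return list with `table` (per-gene data.frame joining both screens,
#'   plus `is_diff`) and `diff_genes` (sorted union of DEGs and DEVGs).
#' @export
differential_screen <- function(expr, fdr_max = 0.05, fc_min = 1,
                                n_null = 1000, n_perm = 300, rng_seed = 1) {
  deg <- sam_deg(expr, fdr_max = fdr_max, fc_min = fc_min, n_perm = n_perm,
                 rng_seed = rng_seed)
  devg <- devg_screen(expr, n_null = n_null, fdr_max = fdr_max,
                      rng_seed = rng_seed + 1)
  tab <- merge(deg, devg, by = "gene", sort = TRUE)
  tab$is_diff <- tab$is_deg | tab$is_devg
  list(table = tab,
       diff_genes = differential_union(tab$gene[tab$is_deg],
                                       tab$gene[tab$is_devg]))
}
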
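#' Hypergeometric gene-set enrichment of a module
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when `|module|` genes are sampled from the
#' universe; p-values are BH-adjusted across sets and rows below `fdr_max`
#' are flagged. A local, offline stand-in for web enrichment services.
#'
#' @param module a [gene_module] (or plain character vector of genes).
#' @param gene_sets named list set -> genes (see [read_gene_sets] /
#'   [sets_from_annotation_map]).
#' @param universe character vector of background genes; must contain the
#'   module genes.
#' @param fdr_max adjusted-p threshold (default 0.05).
#' @return data.frame with columns `set`, `overlap`, `set_size`,
#'   `module_size`, `p`, `p_adj`, `significant`, ordered by `p`.
#' @export
hypergeometric_enrichment <- function(module, gene_sets, universe,
                                      fdr_max = 0.05) {
  genes <- if (inherits(module, "gene_module")) module$genes else
    unique(as.character(module))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) {
    abort_riskmod("empty universe", "riskmod_config_error")
  }
  if (!all(genes %in% universe)) {
    abort_riskmod("universe must contain all module genes",
                  "riskmod_config_error")
  }
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, module_size = n,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdr_max
  out[order(out$p, out$set), , drop = FALSE]
}
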
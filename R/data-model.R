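#' Construct a paired tumor/normal expression matrix
#'
#' The central expression container: a numeric matrix of log2 intensities
#' (genes in rows, samples in columns) together with per-sample condition
#' labels and pair identifiers linking each tumor sample to its matched
#' normal.
#'
#' @param values numeric matrix, genes x samples, with gene symbols as row
#'   names and sample ids as column names; all values finite (log2 scale).
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"tumor"` or `"normal"`) and `pair_id`; one row per column of
#'   `values`.
#' @return an object of class `expression_matrix` with elements `values`
#'   and `samples` (reordered to match the matrix columns).
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_riskmod("expression values must be a numeric matrix",
                  "riskmod_format_error")
  }
  if (any(!is.finite(values))) {
    abort_riskmod("expression values must be finite",
                  "riskmod_format_error")
  }
  genes <- rownames(values)
  if (is.null(genes) || anyDuplicated(genes)) {
    abort_riskmod("gene ids must be unique non-null row names",
                  "riskmod_format_error")
  }
  need <- c("sample_id", "condition", "pair_id")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    abort_riskmod(
      "sample annotation needs columns sample_id, condition, pair_id",
      "riskmod_format_error")
  }
  samples <- data.frame(lapply(samples[need], as.character),
                        stringsAsFactors = FALSE)
  ids <- colnames(values)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort_riskmod("sample ids must be unique non-null column names",
                  "riskmod_format_error")
  }
  missing <- setdiff(ids, samples$sample_id)
  if (length(missing) > 0) {
    abort_riskmod(paste0("samples missing from annotation: ",
                         paste(missing, collapse = ", ")),
                  "riskmod_format_error")
  }
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$condition %in% c("tumor", "normal"))) {
    abort_riskmod("conditions must be 'tumor' or 'normal'",
                  "riskmod_format_error")
  }
  # every pair id must occur exactly once per condition
  tab <- table(samples$pair_id, samples$condition)
  bad <- rownames(tab)[tab[, "tumor"] != 1 | tab[, "normal"] != 1]
  if (length(bad) > 0) {
    abort_riskmod(paste0("unpaired or duplicated pair ids: ",
                         paste(bad, collapse = ", ")),
                  "riskmod_pairing_error")
  }
  if (nrow(tab) < 3) {
    abort_riskmod("at least 3 tumor/normal pairs are required",
                  "riskmod_pairing_error")
  }
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d pairs)\n",
              nrow(x$values), ncol(x$values), n_pairs(x)))
  invisible(x)
}

#' Number of tumor/normal pairs
#' @param expr an `expression_matrix`.
#' @return integer pair count.
#' @export
n_pairs <- function(expr) {
  length(unique(expr$samples$pair_id))
}

#' Expression submatrix for one condition
#'
#' Columns are ordered by pair id, so column j of the tumor submatrix is
#' paired with column j of the normal submatrix.
#'
#' @param expr an `expression_matrix`.
#' @param condition `"tumor"` or `"normal"`.
#' @return numeric matrix, genes x pairs.
#' @export
condition_matrix <- function(expr, condition) {
  sel <- expr$samples$condition == condition
  sub <- expr$values[, sel, drop = FALSE]
  ord <- order(expr$samples$pair_id[sel])
  sub[, ord, drop = FALSE]
}

# genes x pairs matrix of within-pair tumor - normal differences
paired_differences <- function(expr) {
  condition_matrix(expr, "tumor") - condition_matrix(expr, "normal")
}

#' Construct an undirected gene-interaction network
#'
#' @param edges data.frame (or 2-column matrix) of gene-symbol pairs; self
#'   loops are rejected, duplicate edges collapsed, endpoint order
#'   normalized.
#' @param seeds character vector of seed-gene symbols (flags nodes present
#'   in the network; absent seeds are ignored).
#' @return an object of class `interaction_network` with elements `nodes`,
#'   `edges` (data.frame `from`/`to` with `from < to`) and `is_seed`
#'   (named logical). Every node has degree >= 1 by construction.
#' @export
interaction_network <- function(edges, seeds = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) {
    abort_riskmod("edge list must have two columns", "riskmod_format_error")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (any(a == b)) {
    abort_riskmod("self loops are not allowed", "riskmod_format_error")
  }
  from <- pmin(a, b)
  to <- pmax(a, b)
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = from[keep], to = to[keep],
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  if (length(nodes) == 0) {
    abort_riskmod("network has no edges", "riskmod_empty_network_error")
  }
  is_seed <- setNames(nodes %in% seeds, nodes)
  structure(list(nodes = nodes, edges = edges, is_seed = is_seed),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes (%d seeds), %d edges\n",
              length(x$nodes), sum(x$is_seed), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of an interaction network
#' @param network an `interaction_network`.
#' @return named integer vector over all nodes.
#' @export
network_degrees <- function(network) {
  counts <- table(c(network$edges$from, network$edges$to))
  out <- setNames(integer(length(network$nodes)), network$nodes)
  out[names(counts)] <- as.integer(counts)
  out
}

network_to_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

# edges of `network` with both endpoints in `genes`
induced_edges <- function(edges, genes) {
  edges[edges$from %in% genes & edges$to %in% genes, , drop = FALSE]
}

#' Construct a gene module
#'
#' A module is a gene set partitioned into seed genes (C1) and non-seed
#' genes (C2) plus its induced edge set; it is the unit flowing through
#' clique merging, pruning and scoring.
#'
#' @param genes character vector (>= 2 genes).
#' @param seeds character vector; `C1 = intersect(genes, seeds)`.
#' @param edges data.frame `from`/`to`, the induced edges.
#' @param label free-text module label.
#' @return an object of class `gene_module` with elements `label`, `genes`,
#'   `seed_genes`, `nonseed_genes`, `edges`.
#' @export
gene_module <- function(genes, seeds, edges, label = "module") {
  genes <- sort(unique(as.character(genes)))
  if (length(genes) < 2) {
    abort_riskmod("a module needs at least 2 genes", "riskmod_format_error")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 &&
      !all(c(edges$from, edges$to) %in% genes)) {
    abort_riskmod("module edges must reference module genes",
                  "riskmod_format_error")
  }
  C1 <- intersect(genes, seeds)
  structure(list(label = as.character(label), genes = genes,
                 seed_genes = C1, nonseed_genes = setdiff(genes, C1),
                 edges = edges),
            class = "gene_module")
}

#' Build a module from a parent network
#'
#' @param network an `interaction_network`; its seed flags define C1 and
#'   its edges are induced onto the gene set.
#' @param genes module gene set (must be network nodes).
#' @param label module label.
#' @return a `gene_module`.
#' @export
gene_module_from_network <- function(network, genes, label = "module") {
  genes <- unique(as.character(genes))
  if (!all(genes %in% network$nodes)) {
    abort_riskmod("module genes must be network nodes",
                  "riskmod_lookup_error")
  }
  seeds <- names(network$is_seed)[network$is_seed]
  gene_module(genes, seeds, induced_edges(network$edges, genes), label)
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene_module '%s': %d genes (%d seeds), %d edges\n",
              x$label, length(x$genes), length(x$seed_genes),
              nrow(x$edges)))
  invisible(x)
}
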
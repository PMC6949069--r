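#' Read a seed-gene membership table
#'
#' TSV with a `gene` column followed by one 0/1 column per source database
#' (e.g. CGC, TGDB, ONGene, NCG). Each gene must be flagged in at least one
#' source and gene symbols must be unique.
#'
#' @param path TSV path.
#' @return data.frame with column `gene` plus one logical column per source.
#' @export
read_seed_membership <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab) || ncol(tab) < 2) {
    abort_riskmod("membership table needs a 'gene' column plus sources",
                  "riskmod_parse_error")
  }
  if (anyDuplicated(tab$gene)) {
    abort_riskmod("duplicate genes in membership table",
                  "riskmod_format_error")
  }
  src <- names(tab)[names(tab) != "gene"]
  for (s in src) {
    tab[[s]] <- as.logical(as.integer(tab[[s]]))
  }
  if (any(rowSums(as.matrix(tab[src])) == 0)) {
    abort_riskmod("every gene must belong to at least one source",
                  "riskmod_format_error")
  }
  tab
}

#' Select seed genes supported by multiple source databases
#'
#' Keeps genes flagged in at least `min_sources` databases; a gene known to
#' several independent disease-gene catalogues is trusted as a seed.
#'
#' @param table membership data.frame from [read_seed_membership] (column
#'   `gene` plus logical source columns).
#' @param min_sources minimum number of supporting databases (default 2).
#' @return character vector of seed genes, sorted lexicographically.
#' @export
select_seed_genes <- function(table, min_sources = 2) {
  if (!is.numeric(min_sources) || min_sources < 1) {
    abort_riskmod("min_sources must be >= 1", "riskmod_config_error")
  }
  if (nrow(table) == 0) {
    return(character(0))
  }
  src <- names(table)[names(table) != "gene"]
  counts <- rowSums(as.matrix(table[src]))
  sort(table$gene[counts >= min_sources])
}

#' Extract the seed-centered subnetwork
#'
#' Retains every edge with at least one seed endpoint, then adds all edges
#' among the retained node set, so cliques among seed neighbors survive.
#' Isolated nodes are dropped.
#'
#' @param full_network an [interaction_network].
#' @param seeds character vector of seed genes.
#' @return an [interaction_network] with `is_seed` set from `seeds`.
#' @export
extract_seed_network <- function(full_network, seeds) {
  present <- intersect(seeds, full_network$nodes)
  if (length(present) == 0) {
    abort_riskmod("no seed gene present in the network",
                  "riskmod_empty_network_error")
  }
  e <- full_network$edges
  incident <- e$from %in% present | e$to %in% present
  if (!any(incident)) {
    abort_riskmod("no edge touches a seed gene",
                  "riskmod_empty_network_error")
  }
  retained <- unique(c(e$from[incident], e$to[incident]))
  interaction_network(induced_edges(e, retained), seeds = present)
}
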
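#' Enumerate size-bounded cliques
#'
#' Returns all maximal cliques with size in `[min_size, max_size]`; maximal
#' cliques larger than `max_size` contribute every one of their
#' `max_size`-gene subsets, so dense regions are not silently dropped. The
#' result is deduplicated and each clique is a sorted gene vector.
#'
#' @param network an [interaction_network].
#' @param min_size smallest clique size kept (default 5).
#' @param max_size largest clique size kept (default 8).
#' @return list of sorted character vectors, ordered deterministically.
#' @export
enumerate_cliques <- function(network, min_size = 5, max_size = 8) {
  if (min_size < 2 || min_size > max_size) {
    abort_riskmod("need 2 <= min_size <= max_size", "riskmod_config_error")
  }
  if (length(network$nodes) == 0 || nrow(network$edges) == 0) {
    return(list())
  }
  g <- network_to_igraph(network)
  maximal <- igraph::max_cliques(g, min = min_size)
  out <- list()
  for (mc in maximal) {
    members <- sort(names(mc))
    if (length(members) <= max_size) {
      out[[length(out) + 1L]] <- members
    } else {
      subs <- combn(members, max_size, simplify = FALSE)
      out <- c(out, subs)
    }
  }
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out <- out[!duplicated(keys)]
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

#' Keep cliques anchored on seeds and containing differential genes
#'
#' @param cliques list of gene vectors.
#' @param seeds seed-gene symbols.
#' @param diff_genes differential-gene symbols.
#' @return the cliques containing >= 1 seed gene and >= 1 differential
#'   gene.
#' @export
filter_cliques <- function(cliques, seeds, diff_genes) {
  keep <- vapply(cliques, function(cl) {
    any(cl %in% seeds) && any(cl %in% diff_genes)
  }, logical(1))
  cliques[keep]
}

#' Simpson overlap index of two gene sets
#'
#' `S(A, B) = |A intersect B| / min(|A|, |B|)`; 1 when one set contains the
#' other, 0 when disjoint.
#'
#' @param A,B nonempty character vectors.
#' @return overlap in [0, 1].
#' @export
simpson_index <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  if (length(A) == 0 || length(B) == 0) {
    abort_riskmod("Simpson index is undefined for empty sets",
                  "riskmod_undefined_index_error")
  }
  length(intersect(A, B)) / min(length(A), length(B))
}

#' Merge overlapping cliques into primary modules
#'
#' Iteratively merges the pair of subgraphs whose SEED-gene subsets have
#' the largest Simpson overlap, as long as that overlap exceeds
#' `threshold` (strict). Ties are broken by the lexicographically smallest
#' combined gene set, so the procedure is deterministic. Merging unions
#' the gene sets and recomputes induced edges from the parent network.
#'
#' @param cliques list of gene vectors (normally from [filter_cliques], so
#'   every clique contains a seed).
#' @param network the parent [interaction_network]; provides seed flags
#'   and induced edges.
#' @param threshold Simpson cutoff in (0, 1]; pairs with `S > threshold`
#'   merge (default 0.8).
#' @return list of [gene_module] objects labeled `M1`, `M2`, ... by
#'   decreasing size.
#' @export
merge_cliques <- function(cliques, network, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) {
    abort_riskmod("threshold must be in (0, 1]", "riskmod_config_error")
  }
  seeds <- names(network$is_seed)[network$is_seed]
  groups <- lapply(cliques, function(cl) {
    list(genes = sort(unique(cl)), seeds = sort(intersect(cl, seeds)))
  })
  empty_seed <- vapply(groups, function(g) length(g$seeds) == 0, logical(1))
  if (any(empty_seed)) {
    abort_riskmod("every clique must contain a seed gene before merging",
                  "riskmod_config_error")
  }
  # cliques with identical seed subsets always have S = 1 and merging them
  # changes no other pair's S (S depends on seed sets only), so they can be
  # coalesced up front; this collapses the clique explosion inside dense
  # regions without altering the fixpoint
  seed_key <- vapply(groups, function(g) paste(g$seeds, collapse = "\r"),
                     character(1))
  groups <- lapply(split(groups, seed_key), function(gs) {
    list(genes = sort(unique(unlist(lapply(gs, `[[`, "genes")))),
         seeds = gs[[1]]$seeds)
  })
  names(groups) <- NULL
  repeat {
    n <- length(groups)
    if (n < 2) break
    best_s <- -Inf
    best_pair <- NULL
    best_key <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- simpson_index(groups[[i]]$seeds, groups[[j]]$seeds)
        if (s <= threshold || s < best_s) next
        key <- paste(sort(union(groups[[i]]$genes, groups[[j]]$genes)),
                     collapse = "\r")
        if (s > best_s || key < best_key) {
          best_s <- s
          best_pair <- c(i, j)
          best_key <- key
        }
      }
    }
    if (is.null(best_pair)) break
    merged <- list(
      genes = sort(union(groups[[best_pair[1]]]$genes,
                         groups[[best_pair[2]]]$genes)),
      seeds = sort(union(groups[[best_pair[1]]]$seeds,
                         groups[[best_pair[2]]]$seeds)))
    groups <- c(groups[-best_pair], list(merged))
  }
  sizes <- vapply(groups, function(g) length(g$genes), integer(1))
  keys <- vapply(groups, function(g) paste(g$genes, collapse = "\r"),
                 character(1))
  groups <- groups[order(-sizes, keys)]
  lapply(seq_along(groups), function(i) {
    gene_module_from_network(network, groups[[i]]$genes,
                             label = paste0("M", i))
  })
}
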
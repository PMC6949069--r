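# In-code fixtures and independent oracles shared across test files.

# minimal paired expression matrix from a genes x (2P) value matrix;
# first P columns tumor, last P normal, pair j = columns (j, P + j)
make_expr <- function(values, genes = NULL) {
  P <- ncol(values) / 2
  if (is.null(genes)) {
    genes <- sprintf("g%02d", seq_len(nrow(values)))
  }
  rownames(values) <- genes
  colnames(values) <- c(sprintf("T%02d", seq_len(P)),
                        sprintf("N%02d", seq_len(P)))
  samples <- data.frame(
    sample_id = colnames(values),
    condition = rep(c("tumor", "normal"), each = P),
    pair_id = rep(sprintf("P%02d", seq_len(P)), 2))
  expression_matrix(values, samples)
}

# expression with given per-condition vectors for a single gene plus
# filler genes so the pairing invariant (>= 3 pairs) holds
expr_one_gene <- function(tumor, normal, fill = 2) {
  P <- length(tumor)
  vals <- rbind(matrix(c(tumor, normal), nrow = 1),
                matrix(8, nrow = fill, ncol = 2 * P))
  make_expr(vals, genes = c("target", sprintf("fill%d", seq_len(fill))))
}

# complete graph over the given genes
complete_network <- function(genes, seeds = character()) {
  e <- t(combn(genes, 2))
  interaction_network(data.frame(from = e[, 1], to = e[, 2]), seeds = seeds)
}

# Erdos-Renyi G(n, p) as an interaction_network (isolated nodes dropped
# by construction)
random_network <- function(n, p, seed) {
  set.seed(seed)
  genes <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < p
  interaction_network(data.frame(from = pairs[keep, 1],
                                 to = pairs[keep, 2]))
}

# independent clique oracle: depth-first enumeration of ALL cliques with
# size <= max_size from a plain adjacency list, then the same size filter
# as the library rule (window cliques that are maximal, plus all cliques
# of exactly max_size)
brute_force_cliques <- function(network, min_size, max_size) {
  nodes <- sort(network$nodes)
  adj <- setNames(lapply(nodes, function(v) {
    sort(c(network$edges$to[network$edges$from == v],
           network$edges$from[network$edges$to == v]))
  }), nodes)
  all_cliques <- list()
  grow <- function(clique, cands) {
    for (v in cands) {
      if (all(clique %in% adj[[v]])) {
        cl2 <- c(clique, v)
        all_cliques[[length(all_cliques) + 1L]] <<- cl2
        if (length(cl2) < max_size) {
          grow(cl2, cands[cands > v])
        }
      }
    }
  }
  grow(character(0), nodes)
  keep <- Filter(function(cl) {
    n <- length(cl)
    if (n < min_size || n > max_size) {
      return(FALSE)
    }
    is_max <- !any(vapply(setdiff(nodes, cl), function(v) {
      all(cl %in% adj[[v]])
    }, logical(1)))
    is_max || n == max_size
  }, all_cliques)
  keep <- lapply(keep, sort)
  keys <- vapply(keep, paste, character(1), collapse = "|")
  keep <- keep[!duplicated(keys)]
  keep[order(vapply(keep, paste, character(1), collapse = "|"))]
}

# vectors with an exact given sample correlation (Gram-Schmidt)
exact_corr_pair <- function(n, rho, seed) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  x <- as.numeric(scale(x))
  z <- residuals(lm(z ~ x))
  z <- as.numeric(scale(z))
  list(x = x, y = rho * x + sqrt(1 - rho^2) * z)
}

# small default study used by several test files (cached per session)
.default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(simulation_config(rng_seed = 1))
    }
    cache
  }
})
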
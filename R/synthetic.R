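#' Describe one planted module for the simulator
#'
#' @param n_module_seeds seed genes assigned to the module.
#' @param n_coherent_nonseeds co-regulated non-seed genes.
#' @param rho within-module equicorrelation in tumor samples, in [0, 1).
#' @param rho_normal within-module equicorrelation in normal samples
#'   (default `rho`); setting it below `rho` plants condition-dependent
#'   rewiring that drives the dPCC score.
#' @param diff_shift tumor-minus-normal mean shift in log2 units.
#' @param variance_ratio tumor variance / normal variance (> 0).
#' @param annotation_overlap fraction of module genes sharing the
#'   module-specific annotation set, in [0, 1].
#' @return named list describing the module.
#' @export
planted_module <- function(n_module_seeds, n_coherent_nonseeds, rho = 0.8,
                           rho_normal = rho, diff_shift = 1.5,
                           variance_ratio = 3, annotation_overlap = 0.9) {
  for (r in c(rho, rho_normal)) {
    if (r < 0 || r >= 1) {
      abort_riskmod(sprintf("equicorrelation %g outside [0, 1)", r),
                    "riskmod_config_error")
    }
  }
  if (variance_ratio <= 0) {
    abort_riskmod("variance_ratio must be > 0", "riskmod_config_error")
  }
  list(n_module_seeds = n_module_seeds,
       n_coherent_nonseeds = n_coherent_nonseeds, rho = rho,
       rho_normal = rho_normal, diff_shift = diff_shift,
       variance_ratio = variance_ratio,
       annotation_overlap = annotation_overlap)
}

#' Simulation configuration with study-condition defaults
#'
#' The default study emulates a paired tumor/normal microarray cohort on a
#' seed-centered interaction network: 500 independent background genes, 32
#' seed genes (the seed-catalogue size of the emulated study; seeds outside
#' planted modules stay unshifted), 43 tumor/normal pairs of log2
#' intensities around 8 with noise sd 0.5, one coherent planted module
#' (6 seeds + 10 non-seeds, tumor equicorrelation 0.3 rewired from 0.05 in
#' normals, +1.2 log2 tumor shift, tumor variance quadrupled, 90% shared
#' annotations) and one decoy module whose genes are variance-inflated
#' (ratio 6) but unshifted, uncorrelated and unannotated — it passes the
#' differential filter yet should fail the risk scores, so only the
#' coherent module survives all three.
#'
#' @param n_background_genes independent background genes.
#' @param n_seeds total seed genes (planted modules draw from this pool).
#' @param planted_modules list of [planted_module] descriptions.
#' @param n_pairs tumor/normal pairs (>= 5).
#' @param noise_sd per-gene noise sd in log2 units.
#' @param edge_prob_background probability of a background edge between
#'   any two genes.
#' @param rng_seed integer master seed; every generator derives from it.
#' @return named list of class `simulation_config`.
#' @export
simulation_config <- function(n_background_genes = 500, n_seeds = 32,
                              planted_modules = list(
                                planted_module(6, 10, rho = 0.3,
                                               rho_normal = 0.05,
                                               diff_shift = 1.2,
                                               variance_ratio = 4,
                                               annotation_overlap = 0.9),
                                planted_module(3, 6, rho = 0,
                                               rho_normal = 0,
                                               diff_shift = 0,
                                               variance_ratio = 6,
                                               annotation_overlap = 0)),
                              n_pairs = 43, noise_sd = 0.5,
                              edge_prob_background = 0.02, rng_seed = 1) {
  if (n_pairs < 5) {
    abort_riskmod("n_pairs must be >= 5", "riskmod_config_error")
  }
  used_seeds <- sum(vapply(planted_modules, `[[`, numeric(1),
                           "n_module_seeds"))
  if (used_seeds > n_seeds) {
    abort_riskmod("planted modules require more seeds than n_seeds",
                  "riskmod_config_error")
  }
  structure(list(n_background_genes = n_background_genes,
                 n_seeds = n_seeds, planted_modules = planted_modules,
                 n_pairs = n_pairs, noise_sd = noise_sd,
                 edge_prob_background = edge_prob_background,
                 rng_seed = rng_seed),
            class = "simulation_config")
}

sim_gene_names <- function(config) {
  seeds <- sprintf("SEED%02d", seq_len(config$n_seeds))
  background <- sprintf("BG%03d", seq_len(config$n_background_genes))
  mods <- list()
  cursor <- 0
  for (m in seq_along(config$planted_modules)) {
    pm <- config$planted_modules[[m]]
    mseeds <- seeds[cursor + seq_len(pm$n_module_seeds)]
    cursor <- cursor + pm$n_module_seeds
    mnon <- sprintf("M%dG%02d", m, seq_len(pm$n_coherent_nonseeds))
    mods[[m]] <- list(seeds = mseeds, nonseeds = mnon,
                      genes = c(mseeds, mnon))
  }
  all <- c(seeds, background, unlist(lapply(mods, `[[`, "nonseeds")))
  if (anyDuplicated(all)) {
    abort_riskmod("simulation config implies duplicate gene ids",
                  "riskmod_config_error")
  }
  list(seeds = seeds, background = background, modules = mods, all = all)
}

#' Simulate a seed-centered interaction network with planted modules
#'
#' Each planted module is a near-clique (edge probability 0.95) over its
#' seeds and coherent non-seeds; background edges appear with
#' `edge_prob_background`; every non-seed gene is attached to at least one
#' seed, and no node is left isolated — the structural contract of a
#' seed-centered network.
#'
#' @param config a [simulation_config].
#' @return list with `network` (an [interaction_network]) and `truth`
#'   (gene names, per-module membership and the config).
#' @export
simulate_network <- function(config) {
  nm <- sim_gene_names(config)
  genes <- nm$all
  edges <- with_rng_seed(config$rng_seed, {
    from <- character(0)
    to <- character(0)
    add <- function(a, b) {
      from <<- c(from, a)
      to <<- c(to, b)
    }
    for (mod in nm$modules) {
      pairs <- combn(mod$genes, 2)
      keep <- runif(ncol(pairs)) < 0.95
      add(pairs[1, keep], pairs[2, keep])
    }
    # every background gene hangs off a random seed
    add(nm$background, sample(nm$seeds, length(nm$background),
                              replace = TRUE))
    pairs <- combn(genes, 2)
    keep <- runif(ncol(pairs)) < config$edge_prob_background
    add(pairs[1, keep], pairs[2, keep])
    df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
    # planted non-seeds must touch a seed; module near-cliques make this
    # overwhelmingly likely, but enforce the contract
    for (mod in nm$modules) {
      unattached <- mod$nonseeds[vapply(mod$nonseeds, function(g) {
        !any(nm$seeds %in% c(df$to[df$from == g], df$from[df$to == g]))
      }, logical(1))]
      for (g in unattached) {
        df <- rbind(df, data.frame(from = g, to = sample(mod$seeds, 1)))
      }
    }
    # no isolated seeds
    present <- unique(c(df$from, df$to))
    for (g in setdiff(genes, present)) {
      df <- rbind(df, data.frame(from = g,
                                 to = sample(setdiff(nm$seeds, g), 1)))
    }
    df
  })
  network <- interaction_network(edges, seeds = nm$seeds)
  truth <- list(genes = genes, seeds = nm$seeds,
                background = nm$background,
                modules = lapply(seq_along(nm$modules), function(m) {
                  c(nm$modules[[m]], config$planted_modules[[m]])
                }),
                config = config)
  list(network = network, truth = truth)
}

# g x n draws with equicorrelation rho, mean mu, sd sigma
equicorr_draw <- function(g, n, rho, mu, sigma) {
  if (g > 1 && rho < -1 / (g - 1)) {
    abort_riskmod(sprintf("equicorrelation %g not positive definite", rho),
                  "riskmod_config_error")
  }
  common <- matrix(rnorm(n), nrow = g, ncol = n, byrow = TRUE)
  indiv <- matrix(rnorm(g * n), nrow = g, ncol = n)
  mu + sigma * (sqrt(rho) * common + sqrt(1 - rho) * indiv)
}

#' Simulate paired tumor/normal expression with planted signal
#'
#' Background genes are i.i.d. normal(8, `noise_sd`) in both conditions.
#' Planted-module genes are equicorrelated within the module (tumor
#' correlation `rho`, normal correlation `rho_normal`), shifted by
#' `diff_shift` log2 units in tumors, with tumor variance scaled by
#' `variance_ratio` — giving every pipeline statistic (mean shift,
#' variance shift, co-expression, rewiring) a known ground truth.
#'
#' @param network an [interaction_network] from [simulate_network].
#' @param truth ground truth from [simulate_network].
#' @param config the [simulation_config] used to build them.
#' @return an [expression_matrix] over all network nodes.
#' @export
simulate_expression <- function(network, truth, config) {
  genes <- network$nodes
  P <- config$n_pairs
  tumor_ids <- sprintf("T%02d", seq_len(P))
  normal_ids <- sprintf("N%02d", seq_len(P))
  pair_ids <- sprintf("P%02d", seq_len(P))
  vals <- with_rng_seed(config$rng_seed + 1, {
    tum <- matrix(rnorm(length(genes) * P, mean = 8, sd = config$noise_sd),
                  nrow = length(genes), dimnames = list(genes, tumor_ids))
    nor <- matrix(rnorm(length(genes) * P, mean = 8, sd = config$noise_sd),
                  nrow = length(genes), dimnames = list(genes, normal_ids))
    for (mod in truth$modules) {
      mg <- intersect(mod$genes, genes)
      g <- length(mg)
      nor[mg, ] <- equicorr_draw(g, P, mod$rho_normal, 8, config$noise_sd)
      tum[mg, ] <- equicorr_draw(g, P, mod$rho, 8 + mod$diff_shift,
                                 config$noise_sd * sqrt(mod$variance_ratio))
    }
    cbind(tum, nor)
  })
  samples <- data.frame(
    sample_id = c(tumor_ids, normal_ids),
    condition = rep(c("tumor", "normal"), each = P),
    pair_id = c(pair_ids, pair_ids), stringsAsFactors = FALSE)
  expression_matrix(vals, samples)
}

#' Simulate gene-function annotations with planted consistency
#'
#' Background genes draw 1-3 functions from a pool of 50. In each planted
#' module, a fraction `annotation_overlap` of the genes share a
#' module-specific 5-function set (replacing their background draws), so
#' the functional-consistency score has a known signal.
#'
#' @param network an [interaction_network].
#' @param truth ground truth from [simulate_network].
#' @param config the [simulation_config].
#' @return named list gene -> character vector of function ids.
#' @export
simulate_annotations <- function(network, truth, config) {
  genes <- network$nodes
  pool <- sprintf("FN%02d", 1:50)
  with_rng_seed(config$rng_seed + 2, {
    ann <- setNames(lapply(genes, function(g) {
      sample(pool, sample(1:3, 1))
    }), genes)
    for (m in seq_along(truth$modules)) {
      mod <- truth$modules[[m]]
      shared <- sprintf("M%d_FN%02d", m, 1:5)
      mg <- intersect(mod$genes, genes)
      n_shared <- round(mod$annotation_overlap * length(mg))
      if (n_shared > 0) {
        for (g in sample(mg, n_shared)) {
          ann[[g]] <- shared
        }
      }
    }
    ann
  })
}

#' Simulate a complete in-memory study
#'
#' @param config a [simulation_config].
#' @return list with `expr`, `network`, `annotations`, `seeds` and
#'   `truth` (including the planted coherent module's gene set).
#' @export
simulate_study <- function(config = simulation_config()) {
  net <- simulate_network(config)
  expr <- simulate_expression(net$network, net$truth, config)
  ann <- simulate_annotations(net$network, net$truth, config)
  list(expr = expr, network = net$network, annotations = ann,
       seeds = net$truth$seeds, truth = net$truth)
}

#' Write a complete fixture bundle to disk
#'
#' Writes `expression.tsv`, `samples.tsv`, `network.tsv`,
#' `annotations.gmt`, `truth.json`, the simulated seed list (`seeds.txt`,
#' one gene per line) and the transcribed seed-membership table
#' (`seed_membership.tsv`) to `dir`; every file is readable by the
#' package's own readers.
#'
#' @param config a [simulation_config].
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
make_fixture <- function(config, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    abort_riskmod(sprintf("cannot write to '%s'", dir), "riskmod_io_error")
  }
  study <- simulate_study(config)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    network = file.path(dir, "network.tsv"),
    annotations = file.path(dir, "annotations.gmt"),
    truth = file.path(dir, "truth.json"),
    seeds = file.path(dir, "seeds.txt"),
    seed_membership = file.path(dir, "seed_membership.tsv"))
  expr_tab <- data.frame(gene = rownames(study$expr$values),
                         study$expr$values, check.names = FALSE,
                         stringsAsFactors = FALSE)
  utils::write.table(expr_tab, paths$expression, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$expr$samples, paths$samples, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(study$network, paths$network)
  write_gene_sets(sets_from_annotation_map(study$annotations),
                  paths$annotations)
  jsonlite::write_json(
    list(seeds = study$seeds,
         modules = lapply(study$truth$modules, function(m) {
           list(genes = m$genes, seeds = m$seeds, nonseeds = m$nonseeds)
         })),
    paths$truth, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  writeLines(study$seeds, paths$seeds)
  file.copy(system.file("extdata", "table6_seed_membership.tsv",
                        package = "riskmod"),
            paths$seed_membership, overwrite = TRUE)
  invisible(paths)
}
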
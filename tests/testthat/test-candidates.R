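test_that("KSG mutual information tracks the Gaussian closed form", {
  # independence: near zero; strong dependence: near -0.5*log(1-rho^2)
  est <- vapply(1:5, function(r) {
    set.seed(r)
    x <- rnorm(600)
    y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(600)
    ksg_mutual_information(x, y, rng_seed = r)
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.5 * log(1 - 0.64))), 0.1)

  est0 <- vapply(1:5, function(r) {
    set.seed(r + 50)
    ksg_mutual_information(rnorm(600), rnorm(600), rng_seed = r)
  }, numeric(1))
  expect_lt(abs(mean(est0)), 0.08)

  # functional dependence blows up with N
  set.seed(2)
  x <- rnorm(1000)
  expect_gte(ksg_mutual_information(x, x, rng_seed = 1), 2)

  expect_error(ksg_mutual_information(1:10, 1:9),
               class = "riskmod_input_error")
  expect_error(ksg_mutual_information(1:4, 1:4, k = 3),
               class = "riskmod_input_error")
})

test_that("Pearson correlation matches hand values and rejects degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_correlation(x, rep(2, 4)),
               class = "riskmod_undefined_correlation_error")
})

test_that("gene objectives rank a seed-identical profile highest", {
  set.seed(11)
  P <- 30
  seed_prof <- rnorm(2 * P, 8, 1)
  genes <- c("seed", "copy", "z1", "z2", "z3")
  vals <- rbind(seed_prof,
                seed_prof + rnorm(2 * P, 0, 0.01), # near-copy of the seed
                matrix(rnorm(3 * 2 * P, 8, 1), nrow = 3))
  expr <- make_expr(vals, genes = genes)
  net <- complete_network(genes, seeds = "seed")
  mod <- gene_module_from_network(net, genes, "T")
  obj <- gene_objectives(mod, expr, rng_seed = 1)
  expect_equal(obj$gene[which.max(obj$pcc_avg)], "copy")
  expect_equal(obj$gene[which.max(obj$mi_sum)], "copy")
  expect_gt(obj$pcc_avg[obj$gene == "copy"], 0.99)
  # independent decoys: near-zero similarity
  expect_lt(max(obj$mi_sum[obj$gene != "copy"]), 0.35)
  expect_error(gene_objectives(
    gene_module(c("ghost", "z1"), "ghost",
                data.frame(from = "ghost", to = "z1")), expr),
    class = "riskmod_config_error")
})

test_that("pareto pruning follows the dominance analysis", {
  net <- complete_network(c("s", "a", "b", "c"), seeds = "s")
  mod <- gene_module_from_network(net, c("s", "a", "b", "c"), "T")
  obj <- data.frame(gene = c("a", "b", "c"),
                    mi_sum = c(2, 1, 3), pcc_avg = c(0.9, 0.5, 0.4))
  # strict front: b is dominated by a and removed
  pruned <- prune_module(mod, obj, "pareto", dominance_tol = 0)
  expect_setequal(pruned$nonseed_genes, c("a", "c"))
  expect_true("s" %in% pruned$genes)
  # default tolerance keeps singly-dominated b
  pruned <- prune_module(mod, obj, "pareto")
  expect_setequal(pruned$nonseed_genes, c("a", "b", "c"))
  # identical objectives: nothing dominated, all retained even at tol 0
  obj$mi_sum <- 1
  obj$pcc_avg <- 0.5
  pruned <- prune_module(mod, obj, "pareto", dominance_tol = 0)
  expect_setequal(pruned$nonseed_genes, c("a", "b", "c"))
  expect_error(prune_module(mod, obj, "nonsense"),
               class = "riskmod_config_error")
})

test_that("quantile pruning keeps genes above both medians", {
  net <- complete_network(c("s", "a", "b", "c", "d"), seeds = "s")
  mod <- gene_module_from_network(net, c("s", "a", "b", "c", "d"), "T")
  obj <- data.frame(gene = c("a", "b", "c", "d"),
                    mi_sum = c(4, 3, 2, 1), pcc_avg = c(0.8, 0.6, 0.4, 0.2))
  pruned <- prune_module(mod, obj, "quantile", quantile_q = 0.5)
  expect_setequal(pruned$nonseed_genes, c("a", "b"))
})

test_that("pruning recovers planted seed-similar genes among decoys", {
  # 5 non-seeds co-regulated with the seeds (rho = 0.8) vs 10 independent
  # decoys: the similar genes survive, the decoys do not
  hits <- vapply(1:3, function(sd) {
    set.seed(sd)
    P <- 40
    n <- 2 * P
    common <- rnorm(n)
    mk <- function() sqrt(0.8) * common + sqrt(0.2) * rnorm(n)
    vals <- rbind(t(replicate(2, mk())), t(replicate(5, mk())),
                  matrix(rnorm(10 * n), nrow = 10)) + 8
    genes <- c(paste0("s", 1:2), paste0("p", 1:5), paste0("d", 1:10))
    expr <- make_expr(vals, genes = genes)
    net <- complete_network(genes, seeds = paste0("s", 1:2))
    mod <- gene_module_from_network(net, genes, "T")
    obj <- gene_objectives(mod, expr, rng_seed = sd)
    pruned <- prune_module(mod, obj)
    c(planted = sum(grepl("^p", pruned$nonseed_genes)),
      decoys = sum(grepl("^d", pruned$nonseed_genes)))
  }, numeric(2))
  expect_true(all(hits["planted", ] >= 4))
  expect_true(all(hits["decoys", ] <= 2))
})

test_that("candidate selection drops all-seed modules", {
  net <- complete_network(c("s1", "s2", "s3", "u", "v"),
                          seeds = c("s1", "s2", "s3"))
  mods <- list(
    gene_module_from_network(net, c("s1", "u", "v"), "A"),
    gene_module_from_network(net, c("s1", "s2"), "B"),
    gene_module_from_network(net, c("s2", "v"), "C"),
    gene_module_from_network(net, c("s1", "s3"), "D"),
    gene_module_from_network(net, c("s1", "s2", "u"), "E"),
    gene_module_from_network(net, c("s3", "u"), "F"))
  kept <- select_candidates(mods)
  expect_equal(length(kept), 4)
  expect_equal(length(select_candidates(list())), 0)
  expect_equal(vapply(kept, `[[`, character(1), "label"),
               c("A", "C", "E", "F"))
})
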
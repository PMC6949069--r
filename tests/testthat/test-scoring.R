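test_that("paired differential statistic matches the hand-computed t", {
  # differences (2, 3, 4): t = 3 / (1 / sqrt(3))
  expr <- expr_one_gene(tumor = c(3, 5, 7), normal = c(1, 2, 3))
  expect_equal(gene_diff_statistic(expr, "target"), 3 * sqrt(3),
               tolerance = 1e-12)
  # identical tumor/normal: zero differences, statistic 0
  expr <- expr_one_gene(tumor = c(1, 2, 3), normal = c(1, 2, 3))
  expect_equal(gene_diff_statistic(expr, "target"), 0)
  # constant nonzero differences: degenerate, capped with warning
  expr <- expr_one_gene(tumor = c(2, 3, 4, 5), normal = c(1, 2, 3, 4))
  expect_warning(t_cap <- gene_diff_statistic(expr, "target"), "capped")
  expect_equal(t_cap, 100)
  expect_error(gene_diff_statistic(expr, "nope"),
               class = "riskmod_lookup_error")
})

test_that("MRF module score reproduces the 3-node worked example", {
  # C1 = {s} with f_s = 4; C2 = {u, v}, edges s-u, s-v, u-v (m = 3, k = 3);
  # f_u/d_u = f_v/d_v = 1 so the smoothness penalty vanishes: W = 4/3
  mod <- gene_module(c("s", "u", "v"), seeds = "s",
                     edges = data.frame(from = c("s", "s", "u"),
                                        to = c("u", "v", "v")))
  f <- c(s = 4, u = 2, v = 1)
  deg <- c(s = 2, u = 2, v = 1)
  mi <- function(a, b) 0.5
  expect_equal(mrf_module_score(mod, f, mi, deg), 4 / 3,
               tolerance = 1e-12)
  # the penalty term really is inert here: any MI gives the same W
  expect_equal(mrf_module_score(mod, f, function(a, b) 7, deg), 4 / 3)

  # seeds-only module: W is the seed mean, no penalty
  mod2 <- gene_module(c("s1", "s2"), seeds = c("s1", "s2"),
                      edges = data.frame(from = "s1", to = "s2"))
  expect_equal(mrf_module_score(mod2, c(s1 = 2, s2 = 4), mi, c(s1 = 1, s2 = 1)),
               3)

  # discordant non-seed neighbors are penalized, and more so with MI
  mod3 <- gene_module(c("s", "u", "v"), seeds = "s",
                      edges = data.frame(from = c("s", "u"),
                                         to = c("u", "v")))
  f3 <- c(s = 4, u = 6, v = 0)
  deg3 <- c(s = 1, u = 2, v = 1)
  w_lo <- mrf_module_score(mod3, f3, function(a, b) 0.1, deg3)
  w_hi <- mrf_module_score(mod3, f3, function(a, b) 0.9, deg3)
  expect_lt(w_hi, w_lo)
  # hand value: 4/3 - (1/2) * (6/2 - 0)^2 * 0.1
  expect_equal(w_lo, 4 / 3 - 0.5 * 9 * 0.1, tolerance = 1e-12)
})

test_that("functional consistency averages Jaccard over annotated pairs", {
  mod <- gene_module(c("s", "y"), seeds = "s",
                     edges = data.frame(from = "s", to = "y"))
  ann <- list(s = c("GO:1", "GO:2"), y = c("GO:2", "GO:3"))
  expect_equal(function_consistency(mod, ann), 1 / 3, tolerance = 1e-12)
  # identical annotation sets everywhere: F = 1
  ann2 <- list(s = c("GO:1", "GO:2"), y = c("GO:1", "GO:2"))
  expect_equal(function_consistency(mod, ann2), 1)
  # unannotated members are excluded; nothing annotated gives 0
  expect_equal(function_consistency(mod, list()), 0)
  mod3 <- gene_module(c("s", "y", "z"), seeds = "s",
                      edges = data.frame(from = c("s", "s"),
                                         to = c("y", "z")))
  ann3 <- list(s = "GO:1", y = "GO:1", z = character(0))
  expect_equal(function_consistency(mod3, ann3), 1) # z pair excluded
})

test_that("PCC difference sums absolute correlation changes over pairs", {
  # two genes with tumor correlation exactly 0.9 and normal exactly -0.3
  P <- 20
  tum <- exact_corr_pair(P, 0.9, seed = 1)
  nor <- exact_corr_pair(P, -0.3, seed = 2)
  vals <- rbind(c(tum$x, nor$x), c(tum$y, nor$y)) + 8
  expr <- make_expr(vals, genes = c("g1", "g2"))
  mod <- gene_module(c("g1", "g2"), seeds = "g1",
                     edges = data.frame(from = "g1", to = "g2"))
  expect_equal(pcc_difference(mod, expr), 1.2, tolerance = 1e-9)

  # three genes: exactly choose(3, 2) = 3 pair terms
  set.seed(5)
  vals3 <- matrix(rnorm(3 * 2 * P, 8, 1), nrow = 3)
  expr3 <- make_expr(vals3, genes = c("a", "b", "c"))
  mod3 <- gene_module(c("a", "b", "c"), seeds = "a",
                      edges = data.frame(from = "a", to = "b"))
  ct <- cor(t(condition_matrix(expr3, "tumor")))
  cn <- cor(t(condition_matrix(expr3, "normal")))
  manual <- abs(ct["a", "b"] - cn["a", "b"]) +
    abs(ct["a", "c"] - cn["a", "c"]) +
    abs(ct["b", "c"] - cn["b", "c"])
  expect_equal(pcc_difference(mod3, expr3), manual, tolerance = 1e-12)

  # same joint distribution in both conditions: small dPCC
  set.seed(6)
  big <- make_expr(matrix(rnorm(2 * 2 * 200, 8, 1), nrow = 2),
                   genes = c("a", "b"))
  modb <- gene_module(c("a", "b"), seeds = "a",
                      edges = data.frame(from = "a", to = "b"))
  expect_lt(pcc_difference(modb, big), 0.25)
})

test_that("permutation p-values count the upper tail with add-one", {
  expect_equal(permutation_p(1000, 1:999), 1 / 1000)
  expect_equal(permutation_p(0, 1:999), 1)
  null <- seq(-2, 2, length.out = 101)
  expect_equal(permutation_p(0, null), (1 + 51) / 102)
  # monotone non-increasing in the observed value, bounded in (0, 1]
  obs <- seq(-3, 3, by = 0.5)
  ps <- vapply(obs, permutation_p, numeric(1), null_scores = null)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0 & ps <= 1))
  expect_error(permutation_p(1, numeric(0)), class = "riskmod_input_error")
})

test_that("random modules respect composition, determinism and limits", {
  net <- complete_network(c(sprintf("s%d", 1:4), sprintf("x%d", 1:8)),
                          seeds = sprintf("s%d", 1:4))
  mods <- random_modules(net, n_genes = 5, n_seeds = 2, count = 50,
                         rng_seed = 9)
  expect_equal(length(mods), 50)
  expect_true(all(vapply(mods, function(m) length(m$genes), integer(1)) == 5))
  expect_true(all(vapply(mods, function(m) length(m$seed_genes),
                         integer(1)) == 2))
  mods2 <- random_modules(net, 5, 2, count = 50, rng_seed = 9)
  expect_identical(lapply(mods, `[[`, "genes"),
                   lapply(mods2, `[[`, "genes"))
  expect_error(random_modules(net, 6, 5, count = 10),
               class = "riskmod_sampling_error")
})

test_that("risk identification honors alpha and reports all fields", {
  cfg <- simulation_config(
    n_background_genes = 60, n_seeds = 8,
    planted_modules = list(planted_module(3, 4, rho = 0.3,
                                          rho_normal = 0.05,
                                          diff_shift = 1.2,
                                          variance_ratio = 4,
                                          annotation_overlap = 1)),
    n_pairs = 12, rng_seed = 3)
  s <- simulate_study(cfg)
  mod <- gene_module_from_network(s$network, s$truth$modules[[1]]$genes,
                                  "planted")
  reports <- suppressWarnings(
    identify_risk_modules(list(mod), s$expr, s$annotations, s$network,
                          alpha = 0.05, n_random = 100, rng_seed = 4))
  r <- reports[[1]]
  expect_equal(length(r$null_W), 100)
  expect_equal(length(r$null_F), 100)
  expect_equal(length(r$null_dPCC), 100)
  expect_true(all(c(r$p_W, r$p_F, r$p_dPCC) > 0))
  expect_equal(r$is_risk, r$p_W < 0.05 && r$p_F < 0.05 && r$p_dPCC < 0.05)
  # degenerate threshold: everything is a risk module
  rep1 <- suppressWarnings(
    identify_risk_modules(list(mod), s$expr, s$annotations, s$network,
                          alpha = 1, n_random = 100, rng_seed = 4))
  expect_true(rep1[[1]]$is_risk)
  expect_equal(nrow(risk_summary(reports)), 1)
})
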
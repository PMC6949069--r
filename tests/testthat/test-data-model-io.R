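test_that("expression TSV round trip preserves pairing and values", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "expr.tsv")
  ann <- file.path(dir, "samples.tsv")
  writeLines(c("gene\tT1\tT2\tT3\tN1\tN2\tN3",
               "a\t1\t2\t3\t4\t5\t6",
               "b\t1.5\t2.5\t3.5\t4.5\t5.5\t6.5",
               "c\t0\t0\t0\t0\t0\t0",
               "d\t7\t8\t9\t1\t2\t3"), mat)
  writeLines(c("sample_id\tcondition\tpair_id",
               "T1\ttumor\tp1", "T2\ttumor\tp2", "T3\ttumor\tp3",
               "N1\tnormal\tp1", "N2\tnormal\tp2", "N3\tnormal\tp3"), ann)
  expr <- read_expression(mat, ann)
  expect_equal(ncol(expr$values), 6)
  expect_equal(n_pairs(expr), 3)
  expect_equal(expr$values["a", "T2"], 2)
  tum <- condition_matrix(expr, "tumor")
  nor <- condition_matrix(expr, "normal")
  expect_equal(unname(tum["d", ] - nor["d", ]), c(6, 6, 6))
})

test_that("expression reader rejects unpaired samples and bad cells", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "expr.tsv")
  ann <- file.path(dir, "samples.tsv")
  writeLines(c("gene\tT1\tT2\tT3\tT7\tN1\tN2\tN3",
               paste("a", paste(1:7, collapse = "\t"), sep = "\t")), mat)
  writeLines(c("sample_id\tcondition\tpair_id",
               "T1\ttumor\tp1", "T2\ttumor\tp2", "T3\ttumor\tp3",
               "T7\ttumor\tp7",
               "N1\tnormal\tp1", "N2\tnormal\tp2", "N3\tnormal\tp3"), ann)
  expect_error(read_expression(mat, ann), class = "riskmod_pairing_error")

  writeLines(c("gene\tT1\tT2\tT3\tN1\tN2\tN3",
               "a\t1\toops\t3\t4\t5\t6"), mat)
  writeLines(c("sample_id\tcondition\tpair_id",
               "T1\ttumor\tp1", "T2\ttumor\tp2", "T3\ttumor\tp3",
               "N1\tnormal\tp1", "N2\tnormal\tp2", "N3\tnormal\tp3"), ann)
  expect_error(read_expression(mat, ann), class = "riskmod_parse_error")
})

test_that("duplicate gene rows collapse to the highest-mean row", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "expr.tsv")
  ann <- file.path(dir, "samples.tsv")
  writeLines(c("gene\tT1\tT2\tT3\tN1\tN2\tN3",
               "dup\t5\t5\t5\t5\t5\t5",
               "dup\t7\t7\t7\t7\t7\t7",
               "x\t1\t1\t1\t1\t1\t1"), mat)
  writeLines(c("sample_id\tcondition\tpair_id",
               "T1\ttumor\tp1", "T2\ttumor\tp2", "T3\ttumor\tp3",
               "N1\tnormal\tp1", "N2\tnormal\tp2", "N3\tnormal\tp3"), ann)
  expr <- read_expression(mat, ann)
  expect_equal(sum(rownames(expr$values) == "dup"), 1)
  expect_equal(unname(expr$values["dup", 1]), 7)
})

test_that("seed selection applies the multi-database threshold", {
  tab <- data.frame(gene = c("A", "B"), CGC = c(1, 0), NCG = c(1, 1))
  tab$CGC <- as.logical(tab$CGC)
  tab$NCG <- as.logical(tab$NCG)
  expect_equal(select_seed_genes(tab, 2), "A")
  expect_equal(select_seed_genes(tab, 1), c("A", "B"))
  expect_equal(select_seed_genes(tab[0, ], 2), character(0))
  expect_error(select_seed_genes(tab, 0), class = "riskmod_config_error")
  # monotone: raising the threshold never adds genes
  for (k in 1:3) {
    expect_true(all(select_seed_genes(tab, k + 1) %in%
                      select_seed_genes(tab, k)))
  }
})

test_that("seed-centered extraction keeps edges among seed neighbors", {
  net <- interaction_network(
    data.frame(from = c("S", "S", "S", "a", "x"),
               to = c("a", "b", "c", "b", "y")),
    seeds = "S")
  sub <- extract_seed_network(net, "S")
  expect_setequal(sub$nodes, c("S", "a", "b", "c"))
  expect_equal(nrow(sub$edges), 4) # S-a, S-b, S-c and a-b survive
  expect_true(all(sub$edges$from %in% sub$nodes))
  # x-y has no seed endpoint and no seed-adjacent endpoint: gone
  expect_false(any(sub$edges$from == "x" | sub$edges$to == "x"))
  expect_error(extract_seed_network(net, "Z"),
               class = "riskmod_empty_network_error")
  # every retained node is a seed or adjacent to one
  deg_seed <- c(sub$edges$from[sub$edges$to == "S"],
                sub$edges$to[sub$edges$from == "S"])
  expect_true(all(setdiff(sub$nodes, "S") %in% deg_seed |
                    setdiff(sub$nodes, "S") %in% c("a", "b", "c")))
})

test_that("edge-list and GMT parsers reject malformed lines by number", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "net.tsv")
  writeLines(c("a\tb", "c"), p)
  err <- tryCatch(read_network(p), error = function(e) conditionMessage(e))
  expect_match(err, "line 2")

  g <- file.path(dir, "sets.gmt")
  writeLines(c("S1\tdesc\tg1\tg2", "S2\tdesc\tg2\tg3\tg4"), g)
  sets <- read_gene_sets(g)
  expect_equal(sets$S1, c("g1", "g2"))
  expect_equal(length(sets), 2)
  writeLines("S1\tonly-two-fields", g)
  expect_error(read_gene_sets(g), class = "riskmod_parse_error")
})

test_that("module JSON and GMT writers round-trip through their readers", {
  net <- complete_network(c("s1", "s2", "u", "v"), seeds = c("s1", "s2"))
  mods <- list(gene_module_from_network(net, c("s1", "u", "v"), "M1"),
               gene_module_from_network(net, c("s1", "s2", "u"), "M2"),
               gene_module_from_network(net, c("s2", "v"), "M3"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "mods.json")
  write_modules(mods, p)
  back <- read_modules(p)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$genes, mods[[i]]$genes)
    expect_equal(back[[i]]$seed_genes, mods[[i]]$seed_genes)
    expect_equal(back[[i]]$label, mods[[i]]$label)
    expect_equal(nrow(back[[i]]$edges), nrow(mods[[i]]$edges))
  }
  g <- file.path(dir, "ann.gmt")
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3"))
  write_gene_sets(sets, g)
  expect_equal(read_gene_sets(g), sets)
  # per-gene map inversion is consistent both ways
  ann <- annotation_map_from_sets(sets)
  expect_setequal(ann$g2, c("A", "B"))
  expect_equal(sets_from_annotation_map(ann)[["A"]],
               c("g1", "g2"))
})
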
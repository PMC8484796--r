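test_that("mutation frequencies collapse multi-hit samples", {
  mut <- mutation_table(data.frame(
    sample_id = c("s1", "s2", "s2", "s3"),
    gene_id = c("geneA", "geneA", "geneA", "geneB"),
    variant_classification = c("missense", "missense", "nonsense", "splice_site"),
    stringsAsFactors = FALSE))
  mf <- mutation_frequencies(mut, paste0("s", 1:4), c("geneA", "geneB"))
  a <- mf$per_gene[mf$per_gene$gene_id == "geneA", ]
  expect_equal(a$n_altered, 2)          # s2 counted once despite 2 records
  expect_equal(a$frequency, 0.5)
  expect_equal(a$top_classification, "missense")
  expect_equal(mf$overall$fraction, 3 / 4)
  expect_error(mutation_frequencies(mut, paste0("s", 1:4), character()),
               "non-empty")
})

test_that("simulated mutation frequencies recover the planted rate", {
  samples <- paste0("s", 1:5000)
  mut <- simulate_mutations(c(geneA = 0.11), samples, seed = 61)
  mf <- mutation_frequencies(mut, samples, "geneA")
  f <- mf$per_gene$frequency
  expect_gt(f, 0.095)
  expect_lt(f, 0.125)
})

test_that("CNV gain/loss frequencies use per-gene denominators", {
  cnv <- cnv_table(data.frame(
    sample_id = paste0("s", 1:10),
    gene_id = "geneA",
    call = c(rep("gain", 3), rep("neutral", 7)),
    stringsAsFactors = FALSE))
  cf <- cnv_frequencies(cnv)
  expect_equal(cf$gain_freq, 0.3)
  expect_equal(cf$loss_freq, 0)

  allneutral <- cnv_table(data.frame(sample_id = paste0("s", 1:5),
                                     gene_id = "geneB", call = "neutral",
                                     stringsAsFactors = FALSE))
  cf2 <- cnv_frequencies(allneutral)
  expect_equal(cf2$gain_freq + cf2$loss_freq, 0)

  set.seed(62)
  rnd <- cnv_table(data.frame(
    sample_id = paste0("s", 1:2000), gene_id = "geneC",
    call = sample(c("gain", "neutral"), 2000, TRUE, prob = c(0.4, 0.6)),
    stringsAsFactors = FALSE))
  expect_gt(cnv_frequencies(rnd)$gain_freq, 0.37)
  expect_lt(cnv_frequencies(rnd)$gain_freq, 0.43)
})

test_that("two-group expression tests use exact Wilcoxon and star coding", {
  X <- matrix(rep(c(1, 2, 3, 4), each = 3), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  em <- expression_matrix(X)
  # identical groups: s1/s2 values equal s3/s4 values per gene? use copies
  Xc <- cbind(X[, 1:2], X[, 1:2]); colnames(Xc) <- paste0("s", 1:4)
  same <- two_group_expression_test(expression_matrix(Xc),
                                    rep(c("a", "b"), each = 2))
  expect_true(all(same$p == 1))
  expect_true(all(same$stars == "ns"))

  # x = (1,2), y = (3,4) per gene -> exact p = 1/3
  sep <- two_group_expression_test(em, rep(c("a", "b"), each = 2))
  expect_equal(sep$p, rep(1 / 3, 3), tolerance = 1e-10)

  expect_error(two_group_expression_test(em, c("a", "a", "a", "b")),
               ">= 2 samples")
})

test_that("a planted shift is detected at ~5% background rate", {
  set.seed(63)
  n <- 50; p <- 200
  X <- matrix(rnorm(p * 2 * n), p, 2 * n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:(2 * n))))
  lab <- rep(c("n", "t"), each = n)
  X["g1", lab == "t"] <- X["g1", lab == "t"] + 2
  tab <- two_group_expression_test(expression_matrix(X), lab)
  expect_lt(tab$adj_p[tab$gene == "g1"], 0.05)
  bg_rate <- mean(tab$p[tab$gene != "g1"] < 0.05)
  expect_gt(bg_rate, 0.02); expect_lt(bg_rate, 0.09)
})

test_that("regulator network keeps strong edges and annotates roles from Cox", {
  set.seed(64)
  cox <- read_cox_table()
  reg <- cox$gene_id
  n <- 60
  X <- matrix(rnorm(length(reg) * n), length(reg), n,
              dimnames = list(reg, paste0("s", 1:n)))
  # make KIAA1429 a near-copy of METTL3
  X["KIAA1429", ] <- 2 * X["METTL3", ] + rnorm(n, 0, 1e-6)
  net <- regulator_network(expression_matrix(X), cox, r_threshold = 0.5)
  e <- net$edges
  hit <- e[e$gene_a == "KIAA1429" & e$gene_b == "METTL3", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$r, 1, tolerance = 1e-3)
  expect_equal(hit$sign, "positive")

  nodes <- net$nodes
  expect_equal(nodes$role[nodes$gene_id == "KIAA1429"], "risk")
  expect_equal(nodes$role[nodes$gene_id == "ELAVL1"], "protective")
  expect_equal(nodes$role[nodes$gene_id == "YTHDC2"], "ns")
  expect_equal(nodes$category[nodes$gene_id == "FTO"], "eraser")
  expect_true(all(e$gene_a < e$gene_b))
})

test_that("network edges are invariant to sample order", {
  set.seed(65)
  cox <- read_cox_table()
  reg <- cox$gene_id[1:8]
  n <- 40
  X <- matrix(rnorm(8 * n), 8, n, dimnames = list(reg, paste0("s", 1:n)))
  cox8 <- cox[cox$gene_id %in% reg, ]
  e1 <- regulator_network(expression_matrix(X), cox8, r_threshold = 0.2)$edges
  e2 <- regulator_network(expression_matrix(X[, sample(n)]), cox8,
                          r_threshold = 0.2)$edges
  expect_equal(e1[order(e1$gene_a, e1$gene_b), c("gene_a", "gene_b", "r")],
               e2[order(e2$gene_a, e2$gene_b), c("gene_a", "gene_b", "r")],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Cox-table summary reproduces the published significant set", {
  cox <- read_cox_table()
  s <- summarize_cox_table(cox, alpha = 0.05)
  expect_setequal(s$significant$gene_id, c("ELAVL1", "ALKBH5", "KIAA1429"))
  expect_equal(s$risk_genes, "KIAA1429")
  expect_setequal(s$protective_genes, c("ELAVL1", "ALKBH5"))
  expect_equal(max(s$significant$hazard_ratio), 1.326562)
  # ordered by p ascending
  expect_equal(s$significant$gene_id[1], "ALKBH5")

  all_rows <- summarize_cox_table(cox, alpha = 1 - 1e-12)
  expect_equal(nrow(all_rows$significant), 21)
  expect_error(summarize_cox_table(cox, alpha = 0), "alpha")
})

test_that("significance is monotone in alpha", {
  cox <- read_cox_table()
  s1 <- summarize_cox_table(cox, 0.01)$significant$gene_id
  s2 <- summarize_cox_table(cox, 0.05)$significant$gene_id
  s3 <- summarize_cox_table(cox, 0.3)$significant$gene_id
  expect_true(all(s1 %in% s2))
  expect_true(all(s2 %in% s3))
})
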
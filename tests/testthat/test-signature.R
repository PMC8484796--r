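test_that("prior weight 0 reduces the moderated t to the pooled t", {
  em <- toy_expr(30, 12, seed = 71)
  lab <- rep(c("a", "b"), each = 6)
  de0 <- moderated_t_de(em, lab, prior_df = 0)
  X <- unclass(em)
  for (g in c(1, 10, 30)) {
    tt <- t.test(X[g, lab == "b"], X[g, lab == "a"], var.equal = TRUE)
    expect_equal(de0$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de0$p[g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("the EB route matches limma's moderated statistics", {
  set.seed(72)
  p <- 200; n <- 10
  X <- matrix(rnorm(p * 2 * n, sd = rep(sqrt(rchisq(p, 5) / 5), 2 * n)), p,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:(2 * n))))
  lab <- rep(c("a", "b"), each = n)
  de <- moderated_t_de(expression_matrix(X), lab)
  design <- model.matrix(~ factor(lab))
  fit <- limma::eBayes(limma::lmFit(X, design))
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(de$log2FC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("moderated DE has power on planted fold changes", {
  set.seed(73)
  p <- 1000; n <- 40
  X <- matrix(rnorm(p * 2 * n), p, 2 * n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:(2 * n))))
  lab <- rep(c("a", "b"), each = n)
  planted <- paste0("g", 1:50)
  X[planted, lab == "b"] <- X[planted, lab == "b"] + 1
  de <- moderated_t_de(expression_matrix(X), lab)
  hits <- filter_degs(de)
  expect_gte(sum(planted %in% hits), 45)
})

test_that("DEG filtering uses strict inequalities", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2FC = c(1, 0.5, 2, 0.1),
                   t = 0, p = 0.01,
                   adj_p = c(0.05, 0.01, 0.01, 0.001))
  expect_equal(filter_degs(de), "c")  # a: adj_p not < 0.05; b: |lfc| not > 0.5
})

test_that("random-forest importance recovers informative genes", {
  set.seed(74)
  n <- 100; p <- 105
  X <- matrix(rnorm(p * 2 * n), p, 2 * n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:(2 * n))))
  lab <- rep(c("a", "b"), each = n)
  informative <- paste0("g", 1:5)
  X[informative, lab == "b"] <- X[informative, lab == "b"] + 3
  rf <- rf_importance_select(expression_matrix(X), lab, n_trees = 300, seed = 7)
  expect_true(all(informative %in% rf$gene[1:10]))
  expect_true(all(rf$importance[match(informative, rf$gene)] > 0))
  expect_error(rf_importance_select(expression_matrix(X), rep("a", 2 * n)),
               "single class")
})

test_that("duplicated informative genes both keep positive importance", {
  set.seed(75)
  n <- 100
  X <- matrix(rnorm(52 * 2 * n), 52, 2 * n,
              dimnames = list(paste0("g", 1:52), paste0("s", 1:(2 * n))))
  lab <- rep(c("a", "b"), each = n)
  X["g1", lab == "b"] <- X["g1", lab == "b"] + 3
  X["g2", ] <- X["g1", ] + rnorm(2 * n, 0, 0.05)  # near-duplicate
  rf <- rf_importance_select(expression_matrix(X), lab, n_trees = 400, seed = 8)
  expect_true(all(rf$importance[match(c("g1", "g2"), rf$gene)] > 0))
})

test_that("the survival filter keeps planted prognostic genes", {
  set.seed(76)
  n <- 500
  g1 <- rnorm(n)
  noise <- rnorm(n)
  sv <- simulate_survival(0.8 * g1, lambda = 0.005, censor_rate = 0.2, seed = 9)
  X <- rbind(riskgene = g1, noisegene = noise)
  colnames(X) <- paste0("s", 1:n)
  clin <- data.frame(sample_id = colnames(X), os_time = sv$os_time,
                     os_event = sv$os_event, stringsAsFactors = FALSE)
  model <- prognostic_filter(expression_matrix(X), clin,
                             c("riskgene", "noisegene"), alpha_surv = 0.05)
  expect_true("riskgene" %in% model$genes$gene)
  expect_gt(model$genes$hr[model$genes$gene == "riskgene"], 1)

  all_kept <- prognostic_filter(expression_matrix(X), clin,
                                c("riskgene", "noisegene"),
                                alpha_surv = 1 - 1e-9)
  expect_equal(nrow(all_kept$genes), 2)
})

test_that("pure-noise genes pass the survival filter at the nominal rate", {
  set.seed(77)
  n <- 120
  hits <- vapply(seq_len(300), function(r) {
    g <- rnorm(n)
    sv <- simulate_survival(rep(0, n), lambda = 0.005, censor_rate = 0,
                            seed = 5000 + r)
    fit <- cox_fit(sv$os_time, sv$os_event, g)
    fit$table$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("sign partition is exhaustive, disjoint, and strict about zero", {
  model <- structure(list(genes = data.frame(
    gene = c("g1", "g2", "g3"), beta = c(0.2, -0.3, 0.1),
    hr = exp(c(0.2, -0.3, 0.1)), p = 0.01, stringsAsFactors = FALSE)),
    class = "signature_model")
  m <- partition_by_sign(model)
  expect_equal(m$X, c("g1", "g3"))
  expect_equal(m$Y, "g2")

  pos <- model; pos$genes$beta <- abs(pos$genes$beta)
  mp <- partition_by_sign(pos)
  expect_equal(length(mp$Y), 0)

  zero <- model; zero$genes$beta[2] <- 0
  expect_error(partition_by_sign(zero), "exactly zero")
})

test_that("HR above or below 1 maps to the X or Y side", {
  cox <- read_cox_table()
  model <- structure(list(genes = data.frame(
    gene = cox$gene_id, beta = log(cox$hazard_ratio),
    hr = cox$hazard_ratio, p = cox$p_value, stringsAsFactors = FALSE)),
    class = "signature_model")
  m <- partition_by_sign(model)
  expect_true("KIAA1429" %in% m$X)   # HR 1.326562
  expect_true("ALKBH5" %in% m$Y)     # HR 0.755901
})

test_that("the score is the z-scaled X-minus-Y sum", {
  X <- matrix(c(2, 1, 1, 2), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  model <- structure(list(genes = data.frame(
    gene = c("g1", "g2"), beta = c(1, -1), hr = exp(c(1, -1)), p = 0.01,
    stringsAsFactors = FALSE), X = "g1", Y = "g2",
    scale_mean = NULL, scale_sd = NULL), class = "signature_model")
  sc <- m6a_score(expression_matrix(X), model)
  expect_equal(unname(sc$scores), c(1, -1) / sqrt(2), tolerance = 1e-12)

  # training-mode scores are standardized
  em <- toy_expr(6, 20, seed = 78)
  m2 <- structure(list(genes = NULL, X = c("g1", "g2"), Y = c("g3"),
                       scale_mean = NULL, scale_sd = NULL),
                  class = "signature_model")
  sc2 <- m6a_score(em, m2)
  expect_lt(abs(mean(sc2$scores)), 1e-10)
  expect_lt(abs(sd(sc2$scores) - 1), 1e-10)

  # gene/sample order invariance
  Xp <- unclass(em)[c(4, 2, 6, 1, 3, 5), c(20:1)]
  sc3 <- m6a_score(expression_matrix(Xp), m2)
  expect_equal(sc3$scores[names(sc2$scores)], sc2$scores, tolerance = 1e-12)

  # adding a constant to an X gene leaves z-scores unchanged
  Xs <- unclass(em); Xs["g1", ] <- Xs["g1", ] + 100
  sc4 <- m6a_score(expression_matrix(Xs), m2)
  expect_equal(sc4$scores, sc2$scores, tolerance = 1e-10)

  const <- matrix(1, 1, 4, dimnames = list("g", paste0("s", 1:4)))
  mc <- structure(list(genes = NULL, X = "g", Y = character(),
                       scale_mean = NULL, scale_sd = NULL),
                  class = "signature_model")
  expect_error(m6a_score(expression_matrix(const), mc), "constant")
})

test_that("trained scale parameters and median transfer to new cohorts", {
  em <- toy_expr(4, 30, seed = 79)
  m <- structure(list(genes = NULL, X = c("g1", "g2"), Y = "g3",
                      scale_mean = NULL, scale_sd = NULL),
                 class = "signature_model")
  tr <- m6a_score(em, m)
  new <- toy_expr(4, 10, seed = 80)
  ap <- m6a_score(new, tr$model)
  # application mode reuses training parameters, so scores are not re-centered
  raw_new <- colSums(unclass(new)[c("g1", "g2"), ]) - unclass(new)["g3", ]
  expect_equal(unname(ap$scores),
               unname((raw_new - tr$model$scale_mean) / tr$model$scale_sd),
               tolerance = 1e-12)
})

test_that("median split puts ties in the low group", {
  s1 <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  sp1 <- median_split(s1)
  expect_setequal(names(sp1$group)[sp1$group == "high"], c("s3", "s4"))

  s2 <- setNames(c(1, 2, 2, 3), paste0("s", 1:4))
  sp2 <- median_split(s2)
  expect_equal(sum(sp2$group == "high"), 1)
  expect_equal(sum(sp2$group == "low"), 3)

  expect_warning(sp3 <- median_split(setNames(rep(1, 4), paste0("s", 1:4))),
                 "low group")
  expect_true(all(sp3$group == "low"))
})
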
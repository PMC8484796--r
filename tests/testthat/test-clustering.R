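test_that("well-separated clouds give a crisp consensus matrix", {
  tc <- two_clouds(n_per = 20, sep = 6, seed = 3)
  cc <- consensus_cluster(tc$expr, k_range = 2, reps = 100, seed = 4,
                          scale_genes = FALSE)
  M <- cc$consensus[["2"]]
  within <- c(M[1:20, 1:20][upper.tri(diag(20))],
              M[21:40, 21:40][upper.tri(diag(20))])
  between <- M[1:20, 21:40]
  expect_true(all(within >= 0.95))
  expect_true(all(between <= 0.05))
  expect_equal(adjusted_rand_index(cc$labels[["2"]], tc$truth), 1)
})

test_that("subsample = 1 makes every repetition identical", {
  tc <- two_clouds(n_per = 10, sep = 6, seed = 5)
  cc <- consensus_cluster(tc$expr, k_range = 2, reps = 5, subsample = 1, seed = 9)
  expect_true(all(cc$consensus[["2"]] %in% c(0, 1)))
})

test_that("distance-zero duplicate samples always co-cluster", {
  base <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5),
                                                  paste0("s", 1:4)))
  X <- base[, c(1, 1, 2, 2, 3, 3, 4, 4)]
  colnames(X) <- paste0("d", 1:8)
  cc <- consensus_cluster(expression_matrix(X), k_range = 2, reps = 50,
                          subsample = 1, seed = 2)
  M <- cc$consensus[["2"]]
  for (pair in list(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
    expect_equal(M[pair[1], pair[2]], 1)
})

test_that("consensus matrix is symmetric, bounded, and permutation-equivariant", {
  tc <- two_clouds(n_per = 12, sep = 6, seed = 6)
  cc <- consensus_cluster(tc$expr, k_range = 2, reps = 60, seed = 10,
                          scale_genes = FALSE)
  M <- cc$consensus[["2"]]
  expect_equal(M, t(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(diag(M) == 1))

  perm <- c(13:24, 1:12)
  Xp <- unclass(tc$expr)[, perm]
  ccp <- consensus_cluster(expression_matrix(Xp), k_range = 2, reps = 60,
                           seed = 10, scale_genes = FALSE)
  Mp <- ccp$consensus[["2"]]
  # same pairs, identified by sample id, not position; resampling noise only
  expect_lt(max(abs(Mp[colnames(tc$expr), colnames(tc$expr)] - M)), 0.05)
})

test_that("consensus entries converge with more repetitions on separable data", {
  tc <- two_clouds(n_per = 20, sep = 6, seed = 3)
  c100 <- consensus_cluster(tc$expr, k_range = 2, reps = 100, seed = 1,
                            scale_genes = FALSE)
  c1000 <- consensus_cluster(tc$expr, k_range = 2, reps = 1000, seed = 2,
                             scale_genes = FALSE)
  drift <- max(abs(c100$consensus[["2"]] - c1000$consensus[["2"]]))
  expect_lt(drift, 0.1)
})

test_that("labels are stable across seeds on separable data", {
  tc <- two_clouds(n_per = 15, sep = 6, seed = 20)
  labs <- lapply(1:5, function(s)
    consensus_cluster(tc$expr, k_range = 2, reps = 50, seed = s,
                      scale_genes = FALSE)$labels[["2"]])
  for (i in 2:5)
    expect_equal(adjusted_rand_index(labs[[1]], labs[[i]]), 1)
})

test_that("select_k prefers the planted k and flags noise", {
  # three clusters, pairwise separation >= 6 sd
  set.seed(30)
  n <- 30; p <- 10
  mu <- rbind(c(0, 0, rep(0, p - 2)),
              c(6, 0, rep(0, p - 2)),
              c(3, 3 * sqrt(3), rep(0, p - 2)))
  X <- sapply(seq_len(3 * n), function(j) rnorm(p) + mu[ceiling(j / n), ])
  dimnames(X) <- list(paste0("g", 1:p), paste0("s", 1:(3 * n)))
  cc <- consensus_cluster(expression_matrix(X), k_range = 2:5, reps = 100,
                          seed = 14, scale_genes = FALSE)
  sel <- select_k(cc)
  expect_equal(sel$k, 3)
  expect_true(sel$stable)

  # pure noise: ambiguous everywhere
  noise <- expression_matrix(matrix(rnorm(10 * 40), 10,
                                    dimnames = list(paste0("g", 1:10),
                                                    paste0("s", 1:40))))
  ccn <- consensus_cluster(noise, k_range = 2:3, reps = 60, seed = 15)
  expect_warning(seln <- select_k(ccn), "unstable")
  expect_false(seln$stable)
})

test_that("select_k degenerates gracefully with a single k", {
  tc <- two_clouds(n_per = 10, sep = 6, seed = 40)
  cc <- consensus_cluster(tc$expr, k_range = 2, reps = 30, seed = 3)
  expect_warning(sel <- select_k(cc), "single k")
  expect_equal(sel$k, 2)
})

test_that("cluster naming follows survival when clinical data is present", {
  labels <- setNames(rep(1:2, each = 20), paste0("s", 1:40))
  set.seed(8)
  clin <- data.frame(sample_id = paste0("s", 1:40),
                     os_time = c(rexp(20, 1 / 100), rexp(20, 1 / 1000)),
                     os_event = 1, stringsAsFactors = FALSE)
  named <- name_clusters(labels, clin)
  # cluster 2 survives longer, so it must be called "A"
  expect_true(all(named[labels == 2] == "A"))
  expect_true(all(named[labels == 1] == "B"))
})

test_that("PCA embedding explains variance correctly", {
  # samples on a line: rank-1
  t_ <- seq(-2, 2, length.out = 10)
  X <- rbind(g1 = 2 * t_, g2 = -1 * t_, g3 = 0.5 * t_)
  colnames(X) <- paste0("s", 1:10)
  pe <- pca_embed(expression_matrix(X), 2)
  expect_equal(pe$explained[1], 1, tolerance = 1e-12)

  set.seed(17)
  iso <- matrix(rnorm(2 * 2000), 2, dimnames = list(c("g1", "g2"),
                                                    paste0("s", 1:2000)))
  pi_ <- pca_embed(expression_matrix(iso), 2)
  expect_true(all(pi_$explained > 0.45 & pi_$explained < 0.55))
  expect_true(all(diff(pi_$explained) <= 0))

  expect_error(pca_embed(expression_matrix(
    matrix(1, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))), 1),
    "constant")
})

test_that("planted clusters separate on the first two components", {
  tc <- two_clouds(n_per = 25, sep = 6, seed = 23)
  pe <- pca_embed(tc$expr, 2)
  sil <- cluster::silhouette(tc$truth, dist(pe$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("adjusted Rand index matches its definition on known cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  skip_if_not_installed("mclust")
  set.seed(3)
  a <- sample(1:3, 50, replace = TRUE)
  b <- sample(1:3, 50, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})
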
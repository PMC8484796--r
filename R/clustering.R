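# Resampling consensus clustering of samples with PAC-based model selection
# and a PCA embedding for visual validation of the partition.

#' Resampling consensus clustering
#'
#' For each repetition a random subsample of samples (without replacement) is
#' clustered by agglomerative Ward linkage on Euclidean distance and cut at
#' each k; the consensus matrix entry for a pair is its co-clustering count
#' divided by its co-sampling count. Final labels per k come from average-
#' linkage clustering of 1 - consensus. Genes are z-scored first by default
#' so scale differences across the panel do not dominate the distance.
#'
#' @param expr An [expression_matrix()] (genes x samples); typically already
#'   restricted to the regulator panel.
#' @param k_range Integer vector of cluster counts to evaluate (each >= 2,
#'   < n).
#' @param reps Number of resampling repetitions (>= 1).
#' @param subsample Fraction of samples drawn per repetition, in (0, 1].
#' @param seed Integer seed.
#' @param scale_genes z-score each gene before computing distances (default
#'   TRUE).
#' @param linkage Agglomeration method for the base clusterer (default
#'   `"ward.D2"`).
#' @return List of class `consensus_result`: per-k list `consensus`
#'   (matrices), `labels` (named integer vectors), `cluster_consensus`
#'   (mean within-cluster consensus), plus `pac`, `cdf`, `delta_area`,
#'   and the parameters.
#' @export
consensus_cluster <- function(expr, k_range = 2:6, reps = 1000L, subsample = 0.8,
                              seed = 1L, scale_genes = TRUE, linkage = "ward.D2") {
  X <- .as_plain(expr)
  n <- ncol(X)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]", call. = FALSE)
  if (any(k_range < 2) || any(k_range >= n))
    stop("k_range must satisfy 2 <= k <= n - 1", call. = FALSE)
  if (scale_genes) {
    sds <- apply(X, 1, sd)
    keep <- sds > 0
    if (!all(keep)) {
      warning("dropping ", sum(!keep), " zero-variance gene(s) before clustering",
              call. = FALSE)
      X <- X[keep, , drop = FALSE]
    }
    X <- (X - rowMeans(X)) / apply(X, 1, sd)
  }
  m <- ceiling(subsample * n)
  set.seed(seed)
  draws <- replicate(reps, sort(sample.int(n, m)), simplify = FALSE)

  cosample <- matrix(0, n, n)
  cocluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(cocluster) <- as.character(k_range)
  for (r in seq_len(reps)) {
    j <- draws[[r]]
    cosample[j, j] <- cosample[j, j] + 1
    hc <- hclust(dist(t(X[, j, drop = FALSE]), method = "euclidean"),
                 method = linkage)
    for (k in k_range) {
      lab <- cutree(hc, k = k)
      same <- outer(lab, lab, "==")
      kk <- as.character(k)
      cocluster[[kk]][j, j] <- cocluster[[kk]][j, j] + same
    }
  }
  off <- upper.tri(cosample)
  if (any(cosample[off] == 0))
    stop("some sample pairs were never co-sampled; increase reps", call. = FALSE)

  samples <- colnames(X)
  consensus <- list(); labels <- list(); cc_means <- list()
  pac <- numeric(length(k_range)); names(pac) <- as.character(k_range)
  cdf <- list()
  grid <- seq(0, 1, by = 0.01)
  for (k in k_range) {
    kk <- as.character(k)
    M <- cocluster[[kk]] / cosample
    diag(M) <- 1
    dimnames(M) <- list(samples, samples)
    consensus[[kk]] <- M
    hc <- hclust(as.dist(1 - M), method = "average")
    lab <- cutree(hc, k = k)
    names(lab) <- samples
    labels[[kk]] <- lab
    cc_means[[kk]] <- vapply(seq_len(k), function(cl) {
      j <- which(lab == cl)
      if (length(j) < 2) return(NA_real_)
      mean(M[j, j][upper.tri(M[j, j])])
    }, numeric(1))
    v <- M[off]
    pac[kk] <- mean(v > 0.1 & v < 0.9)
    cdf[[kk]] <- vapply(grid, function(x) mean(v <= x), numeric(1))
  }
  auc <- vapply(cdf, function(f) sum(diff(grid) * f[-1]), numeric(1))
  delta_area <- c(auc[1], diff(auc) / auc[-length(auc)])
  names(delta_area) <- names(auc)

  structure(list(consensus = consensus, labels = labels,
                 cluster_consensus = cc_means,
                 pac = pac, cdf = cdf, cdf_grid = grid, delta_area = delta_area,
                 params = list(k_range = k_range, reps = reps,
                               subsample = subsample, seed = seed,
                               distance = "euclidean", linkage = linkage,
                               scale_genes = scale_genes)),
            class = "consensus_result")
}

#' Choose the number of clusters from a consensus result
#'
#' Returns the k with minimum PAC (proportion of ambiguous consensus entries
#' in (0.1, 0.9)); ties go to the smaller k. The consensus-CDF delta-area is
#' reported as a secondary diagnostic; if even the best PAC exceeds 0.5 the
#' clustering is flagged unstable.
#'
#' @param result A `consensus_result`.
#' @return List with k, pac, delta_area, stable.
#' @export
select_k <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  pac <- result$pac
  if (length(pac) == 1) {
    warning("single k evaluated; returning it without model selection", call. = FALSE)
    k <- as.integer(names(pac))
    return(list(k = k, pac = pac, delta_area = result$delta_area,
                stable = pac[[1]] <= 0.5))
  }
  ks <- as.integer(names(pac))
  best <- ks[which(pac == min(pac))]
  k <- min(best)
  stable <- min(pac) <= 0.5
  if (!stable)
    warning("minimum PAC > 0.5: clustering unstable for every k", call. = FALSE)
  list(k = k, pac = pac, delta_area = result$delta_area, stable = stable)
}

#' Orient two-cluster labels so cluster "A" is the better-survival arm
#'
#' With clinical data, cluster A is the arm with the higher Kaplan-Meier
#' median survival (falling back to mean observed time if a median is
#' undefined); without clinical data, A is the larger cluster.
#'
#' @param labels Named integer cluster labels (1/2).
#' @param clinical Optional clinical data.frame with sample_id, os_time,
#'   os_event.
#' @return Named character vector of "A"/"B" labels.
#' @export
name_clusters <- function(labels, clinical = NULL) {
  stopifnot(length(unique(labels)) == 2)
  if (!is.null(clinical)) {
    i <- match(names(labels), clinical$sample_id)
    med <- vapply(1:2, function(cl) {
      j <- which(labels == cl)
      sf <- survival::survfit(survival::Surv(clinical$os_time[i][j],
                                             clinical$os_event[i][j]) ~ 1)
      m <- unname(summary(sf)$table["median"])
      if (is.na(m)) mean(clinical$os_time[i][j]) else m
    }, numeric(1))
    a_is <- which.max(med)
  } else {
    a_is <- which.max(tabulate(labels, 2))
  }
  out <- ifelse(labels == a_is, "A", "B")
  names(out) <- names(labels)
  out
}

#' PCA embedding of samples
#'
#' Gene-centered singular value decomposition; components are ordered by
#' singular value and signed so the loading with the largest magnitude is
#' positive.
#'
#' @param expr An [expression_matrix()].
#' @param n_components Number of components (<= min(genes, samples)).
#' @return List with `coords` (samples x components), `explained`
#'   (variance fractions, non-increasing), `loadings`.
#' @export
pca_embed <- function(expr, n_components = 2L) {
  X <- .as_plain(expr)
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(genes, samples)", call. = FALSE)
  if (all(apply(X, 1, var) == 0)) stop("constant matrix", call. = FALSE)
  pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  list(coords = coords, explained = expl[seq_len(k)], loadings = rot)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#'
#' @param a,b Label vectors of equal length (any label type).
#' @return ARI in \[-1, 1\]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
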
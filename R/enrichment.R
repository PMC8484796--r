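# Single-sample gene-set scoring (ssGSEA and a kernel-CDF GSVA-style
# variant) plus hypergeometric over-representation analysis.

# ssGSEA enrichment score for one sample. r: per-gene rank statistic
# (average-tie ranks, larger = more expressed); inset: logical membership.
.ssgsea_es <- function(r, inset, alpha) {
  if (all(inset)) return(0)  # P_in and P_out coincide when the set is everything
  ord <- order(r, decreasing = TRUE)
  inset <- inset[ord]
  w <- abs(r[ord])^alpha
  w[!inset] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / sum(!inset)
  sum(p_in - p_out)
}

# GSVA-style score for one sample: signed maximum deviation of the weighted
# in-set vs out-of-set random walk over genes ordered by the sample's
# kernel-CDF rank statistic.
.gsva_es <- function(r, inset) {
  if (all(inset)) return(0)
  ord <- order(r, decreasing = TRUE)
  inset <- inset[ord]
  w <- abs(r[ord])
  w[!inset] <- 0
  v <- cumsum(w) / sum(w) - cumsum(!inset) / sum(!inset)
  v[which.max(abs(v))]
}

#' Single-sample gene-set enrichment scores
#'
#' `method = "ssgsea"`: per sample, genes are ranked by expression
#' (descending, average ranks on ties); the enrichment score is the sum over
#' ranked positions of the difference between the weighted in-set running
#' ECDF (weights `|rank statistic|^alpha`) and the unweighted out-of-set
#' running ECDF. With `normalize = TRUE` all scores are divided by
#' (max - min) over the whole matrix.
#'
#' `method = "gsva"`: per gene, a Gaussian-kernel CDF across samples
#' (bandwidth = per-gene SD / 4) gives a per-sample expression statistic;
#' per sample those statistics are converted to symmetric ranks
#' (|n/2 - rank|-weighted walk) and the score is the signed maximum
#' deviation of the in-set vs out-of-set random walk.
#'
#' Sets are intersected with the matrix genes; sets with no gene present are
#' skipped with a warning.
#'
#' @param expr An [expression_matrix()].
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param method `"ssgsea"` (default) or `"gsva"`.
#' @param alpha Rank-weight exponent for ssGSEA (default 0.25).
#' @param normalize Divide ssGSEA scores by the matrix-wide score range
#'   (default FALSE).
#' @return Numeric matrix, sets x samples, with attributes `method`,
#'   `alpha`, `normalize`.
#' @export
score_gene_sets <- function(expr, sets, method = c("ssgsea", "gsva"),
                            alpha = 0.25, normalize = FALSE) {
  method <- match.arg(method)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (length(sets) == 0) stop("empty gene-set collection", call. = FALSE)
  X <- .as_plain(expr)
  genes <- rownames(X)
  use <- lapply(sets, intersect, genes)
  small <- vapply(use, length, integer(1)) < 1
  if (any(small)) {
    warning("skipping gene set(s) with no genes present: ",
            paste(names(sets)[small], collapse = ", "), call. = FALSE)
    use <- use[!small]
  }
  if (length(use) == 0) stop("no gene set overlaps the matrix", call. = FALSE)
  member <- vapply(use, function(g) genes %in% g, logical(nrow(X)))  # genes x sets

  S <- matrix(NA_real_, nrow = length(use), ncol = ncol(X),
              dimnames = list(names(use), colnames(X)))
  if (method == "ssgsea") {
    for (j in seq_len(ncol(X))) {
      r <- rank(X[, j])  # ties: average ranks; larger = higher expression
      for (s in seq_along(use))
        S[s, j] <- .ssgsea_es(r, member[, s], alpha)
    }
    if (normalize) {
      rng <- max(S) - min(S)
      if (rng > 0) S <- S / rng
    }
  } else {
    # per-gene Gaussian-kernel CDF across samples
    Fhat <- X
    for (g in seq_len(nrow(X))) {
      h <- sd(X[g, ]) / 4
      if (h == 0) h <- 1e-8
      Fhat[g, ] <- vapply(X[g, ], function(x) mean(pnorm((x - X[g, ]) / h)),
                          numeric(1))
    }
    n_g <- nrow(X)
    for (j in seq_len(ncol(X))) {
      rk <- rank(Fhat[, j])
      r <- sign(rk - (n_g + 1) / 2) * abs(rk - (n_g + 1) / 2)
      for (s in seq_along(use))
        S[s, j] <- .gsva_es(r, member[, s])
    }
  }
  structure(S, method = method, alpha = if (method == "ssgsea") alpha else NA_real_,
            normalize = normalize)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p per set for an overlap at least as large as
#' observed, BH-adjusted across sets.
#'
#' @param query Gene list of interest (e.g. DEGs).
#' @param universe Background gene list; query genes outside it are dropped
#'   with a warning.
#' @param sets Named list of gene-id vectors.
#' @return Data frame with set_name, overlap, set_size, query_size,
#'   universe_size, p, q (ordered by p).
#' @export
ora_hypergeometric <- function(query, universe, sets) {
  if (length(query) == 0) stop("empty query gene list", call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  out_q <- setdiff(query, universe)
  if (length(out_q)) {
    warning(length(out_q), " query gene(s) outside the universe dropped", call. = FALSE)
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query genes left in universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  tab[order(tab$p), , drop = FALSE]
}
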
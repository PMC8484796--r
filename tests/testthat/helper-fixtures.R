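# Shared fixture builders; all data is generated in code.

# small genes x samples matrix with unique ids
toy_expr <- function(n_genes = 5, n_samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  expression_matrix(m)
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# two well-separated point clouds in gene space; returns expr + truth labels
two_clouds <- function(n_per = 20, n_genes = 10, sep = 6, seed = 1) {
  set.seed(seed)
  lab <- rep(1:2, each = n_per)
  m <- matrix(rnorm(n_genes * 2 * n_per), nrow = n_genes)
  m[1, lab == 2] <- m[1, lab == 2] + sep
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(2 * n_per)))
  list(expr = expression_matrix(m), truth = lab)
}

# brute-force ssGSEA oracle: explicit loop over ranked positions
ssgsea_oracle <- function(values, set_genes, alpha) {
  genes <- names(values)
  r <- rank(values)
  ord <- order(r, decreasing = TRUE)
  inset <- genes[ord] %in% set_genes
  w <- abs(r[ord])^alpha
  es <- 0
  p_in <- 0; p_out <- 0
  sum_w <- sum(w[inset]); n_out <- sum(!inset)
  for (i in seq_along(ord)) {
    if (inset[i]) p_in <- p_in + w[i] / sum_w else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# two-sided Fisher enumeration oracle: sum of hypergeometric probabilities
# of tables (with the observed margins) no more probable than the observed
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
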
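# Regulator-level descriptive statistics: mutation and CNV frequencies,
# tumor-vs-normal expression tests, the correlation network with prognostic
# annotation, and Cox-table summaries.

#' Per-gene somatic mutation frequencies
#'
#' A sample counts once per gene no matter how many records it has there
#' (multi-hit collapse); the denominator is every assayed sample, mutated or
#' not. The overall row reports the fraction of samples carrying a mutation
#' in any listed gene.
#'
#' @param mut A [mutation_table()].
#' @param all_samples Character vector of all assayed sample ids.
#' @param genes Genes to summarize (non-empty).
#' @return List with `per_gene` (gene_id, n_altered, n_total, frequency,
#'   top_classification) and `overall` (n_samples_altered, n_samples,
#'   fraction).
#' @export
mutation_frequencies <- function(mut, all_samples, genes) {
  if (length(all_samples) == 0) stop("all_samples must be non-empty", call. = FALSE)
  if (length(genes) == 0) stop("gene list must be non-empty", call. = FALSE)
  mut <- mut[mut$sample_id %in% all_samples & mut$gene_id %in% genes, , drop = FALSE]
  n_total <- length(all_samples)
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    sub <- mut[mut$gene_id == g, , drop = FALSE]
    n_alt <- length(unique(sub$sample_id))
    topc <- if (nrow(sub)) names(sort(table(sub$variant_classification),
                                      decreasing = TRUE))[1] else NA_character_
    data.frame(gene_id = g, n_altered = n_alt, n_total = n_total,
               frequency = n_alt / n_total, top_classification = topc,
               stringsAsFactors = FALSE)
  }))
  n_any <- length(unique(mut$sample_id))
  list(per_gene = per_gene,
       overall = data.frame(n_samples_altered = n_any, n_samples = n_total,
                            fraction = n_any / n_total))
}

#' Per-gene CNV gain and loss frequencies
#'
#' Denominated by the samples with any call for that gene.
#'
#' @param cnv A [cnv_table()].
#' @return Data frame with gene_id, n_gain, n_loss, n_total, gain_freq,
#'   loss_freq.
#' @export
cnv_frequencies <- function(cnv) {
  if (nrow(cnv) == 0) stop("empty CNV table", call. = FALSE)
  do.call(rbind, lapply(unique(cnv$gene_id), function(g) {
    sub <- cnv[cnv$gene_id == g, , drop = FALSE]
    n <- nrow(sub)
    data.frame(gene_id = g,
               n_gain = sum(sub$call == "gain"), n_loss = sum(sub$call == "loss"),
               n_total = n,
               gain_freq = sum(sub$call == "gain") / n,
               loss_freq = sum(sub$call == "loss") / n,
               stringsAsFactors = FALSE)
  }))
}

# significance stars on adjusted p, the figure-legend convention
.stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE)
}

#' Two-group per-gene expression comparison
#'
#' Two-sided Wilcoxon rank-sum test per gene with BH adjustment across genes
#' and the standard star coding on the adjusted p.
#'
#' @param expr An [expression_matrix()].
#' @param labels Two-level group labels, one per sample.
#' @return Data frame with gene, median_diff (group2 - group1), p, adj_p,
#'   stars.
#' @export
two_group_expression_test <- function(expr, labels) {
  X <- .as_plain(expr)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("need exactly two groups", call. = FALSE)
  labels <- droplevels(labels)
  g1 <- which(labels == levels(labels)[1])
  g2 <- which(labels == levels(labels)[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  p <- apply(X, 1, function(v)
    suppressWarnings(wilcox.test(v[g1], v[g2])$p.value))
  md <- apply(X, 1, function(v) median(v[g2]) - median(v[g1]))
  adj <- bh_adjust(p)
  data.frame(gene = rownames(X), median_diff = md, p = p, adj_p = adj,
             stars = as.character(.stars(adj)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regulator correlation network with prognostic annotation
#'
#' All pairwise expression correlations (Spearman by default); edges are
#' kept where |r| >= `r_threshold` and the BH-adjusted correlation p < 0.05.
#' Nodes are annotated risk / protective / ns from the univariate Cox table
#' and writer / eraser / reader from the category map.
#'
#' @param expr An [expression_matrix()] restricted to the regulator panel.
#' @param cox Data frame with gene_id, hazard_ratio, p_value covering the
#'   panel.
#' @param r_threshold Minimum |r| for an edge (default 0.3).
#' @param roles Optional data.frame gene_id -> category; defaults to the
#'   packaged writer/eraser/reader map.
#' @param method Correlation method (default `"spearman"`).
#' @param alpha Significance level for the prognostic role (default 0.05).
#' @return List with `edges` (gene_a < gene_b, r, p, q, sign) and `nodes`
#'   (gene_id, role, category).
#' @export
regulator_network <- function(expr, cox, r_threshold = 0.3, roles = NULL,
                              method = c("spearman", "pearson"), alpha = 0.05) {
  method <- match.arg(method)
  X <- .as_plain(expr)
  genes <- rownames(X)
  miss <- setdiff(genes, cox$gene_id)
  if (length(miss))
    stop("Cox table lacks regulator(s): ", paste(miss, collapse = ", "), call. = FALSE)
  const <- apply(X, 1, var) == 0
  if (any(const)) {
    warning("constant gene(s) skipped: ", paste(genes[const], collapse = ", "),
            call. = FALSE)
    X <- X[!const, , drop = FALSE]
    genes <- rownames(X)
  }
  pairs <- which(upper.tri(diag(length(genes))), arr.ind = TRUE)
  edges <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    ct <- suppressWarnings(cor.test(X[a, ], X[b, ], method = method))
    data.frame(gene_a = min(genes[a], genes[b]), gene_b = max(genes[a], genes[b]),
               r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
  }))
  edges$q <- bh_adjust(edges$p)
  keep <- abs(edges$r) >= r_threshold & edges$q < 0.05
  edges <- edges[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  rownames(edges) <- NULL

  if (is.null(roles)) roles <- m6a_regulators()
  i <- match(genes, cox$gene_id)
  role <- ifelse(cox$p_value[i] < alpha,
                 ifelse(cox$hazard_ratio[i] > 1, "risk", "protective"), "ns")
  nodes <- data.frame(gene_id = genes, role = role,
                      category = roles$category[match(genes, roles$gene_id)],
                      stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

#' Summarize a univariate Cox table at a significance level
#'
#' @param cox Data frame with gene_id, hazard_ratio, ci_low, ci_high,
#'   p_value.
#' @param alpha Significance level in (0, 1).
#' @return List with `significant` (rows with p < alpha, ordered by p),
#'   `risk_genes` (HR > 1) and `protective_genes` (HR < 1).
#' @export
summarize_cox_table <- function(cox, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  sig <- cox[cox$p_value < alpha, , drop = FALSE]
  sig <- sig[order(sig$p_value), , drop = FALSE]
  rownames(sig) <- NULL
  list(significant = sig,
       risk_genes = sig$gene_id[sig$hazard_ratio > 1],
       protective_genes = sig$gene_id[sig$hazard_ratio < 1])
}

#' Read a univariate Cox table (gene_id, hazard_ratio, ci_low, ci_high,
#' p_value) from TSV
#' @param path File path; defaults to the packaged regulator Cox table.
#' @return Data frame.
#' @export
read_cox_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "regulator_cox_univariate.tsv",
                        package = "m6ascape")
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "hazard_ratio", "ci_low", "ci_high", "p_value")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("Cox table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$ci_low > df$hazard_ratio | df$hazard_ratio > df$ci_high))
    stop("CI bounds must bracket the hazard ratio", call. = FALSE)
  df
}
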
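# The m6A score signature: moderated-t differential expression between
# modification patterns, random-forest redundancy removal, univariate Cox
# survival filtering, sign partition into gene sets X and Y, the per-sample
# score scale(sum X - sum Y), and the median split.

#' Moderated two-group differential expression
#'
#' Per-gene two-group linear model with empirical-Bayes variance shrinkage:
#' the posterior variance is (d0*s0^2 + dg*sg^2)/(d0 + dg) with
#' hyperparameters d0, s0^2 fitted by method of moments on log sg^2
#' (limma's squeezeVar); the moderated t has d0 + dg degrees of freedom.
#' Setting `prior_df = 0` bypasses shrinkage and gives the textbook pooled
#' two-sample t.
#'
#' @param expr An [expression_matrix()] (log2 scale).
#' @param labels Two-level group labels, one per sample; log2FC is
#'   mean(level 2) - mean(level 1).
#' @param prior_df `"eb"` (default, estimated prior df) or `0` for the
#'   ordinary pooled t.
#' @return Data frame with gene, log2FC, t, p, adj_p plus attributes
#'   `d0`, `s0_2`, `contrast`.
#' @export
moderated_t_de <- function(expr, labels, prior_df = "eb") {
  X <- .as_plain(expr)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("need exactly two groups", call. = FALSE)
  g1 <- which(labels == levels(labels)[1])
  g2 <- which(labels == levels(labels)[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  if (nrow(X) < 10)
    stop("need >= 10 genes to estimate the variance prior", call. = FALSE)
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, g2, drop = FALSE])
  v1 <- apply(X[, g1, drop = FALSE], 1, var)
  v2 <- apply(X[, g2, drop = FALSE], 1, var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  if (all(s2 == 0)) stop("all genes have zero variance", call. = FALSE)
  lfc <- m2 - m1
  se_fac <- sqrt(1 / n1 + 1 / n2)
  if (identical(prior_df, 0) || identical(prior_df, 0L)) {
    tt <- lfc / (sqrt(s2) * se_fac)
    df_t <- rep(dg, length(tt))
    d0 <- 0; s0_2 <- NA_real_
  } else {
    sq <- limma::squeezeVar(s2, df = dg)
    tt <- lfc / (sqrt(sq$var.post) * se_fac)
    d0 <- sq$df.prior
    s0_2 <- sq$var.prior
    df_t <- rep(dg + d0, length(tt))
  }
  p <- 2 * pt(-abs(tt), df = pmin(df_t, 1e6))
  out <- data.frame(gene = rownames(X), log2FC = unname(lfc), t = unname(tt),
                    p = unname(p), adj_p = bh_adjust(unname(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "contrast") <- paste(levels(labels)[2], "vs", levels(labels)[1])
  out
}

#' Filter differential-expression results by the signature thresholds
#'
#' Strict inequalities: adj_p < `adj_p_max` and |log2FC| > `lfc_min`.
#'
#' @param de Data frame from [moderated_t_de()].
#' @param adj_p_max Adjusted-p ceiling (default 0.05).
#' @param lfc_min |log2 fold-change| floor (default 0.5).
#' @return Character vector of gene ids.
#' @export
filter_degs <- function(de, adj_p_max = 0.05, lfc_min = 0.5) {
  de$gene[de$adj_p < adj_p_max & abs(de$log2FC) > lfc_min]
}

#' Random-forest importance ranking for redundancy removal
#'
#' Trains a random-forest classifier of the cluster labels on the candidate
#' genes and ranks them by out-of-bag permutation importance (mean decrease
#' in accuracy). The default keep rule retains genes with positive
#' importance.
#'
#' @param expr An [expression_matrix()] restricted to candidate genes.
#' @param labels Cluster labels (factor; >= 2 classes).
#' @param n_trees Number of trees (default 500; < 50 warns).
#' @param seed Integer seed.
#' @param keep_rule `"positive_importance"` (default) or `"top_n"`.
#' @param top_n Number of genes kept under `"top_n"`.
#' @return Data frame gene, importance (mean decrease accuracy), kept —
#'   ordered by importance descending.
#' @export
rf_importance_select <- function(expr, labels, n_trees = 500L, seed = 1L,
                                 keep_rule = c("positive_importance", "top_n"),
                                 top_n = 30L) {
  keep_rule <- match.arg(keep_rule)
  X <- .as_plain(expr)
  if (nrow(X) < 2) stop("need >= 2 candidate genes", call. = FALSE)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("labels contain a single class", call. = FALSE)
  if (n_trees < 50) warning("n_trees < 50: importance estimates will be noisy",
                            call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = t(X), y = y, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)[, 1]  # MeanDecreaseAccuracy
  ord <- order(imp, decreasing = TRUE)
  out <- data.frame(gene = rownames(X)[ord], importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  out$kept <- if (keep_rule == "positive_importance") out$importance > 0
              else seq_len(nrow(out)) <= top_n
  attr(out, "oob_error") <- fit$err.rate[n_trees, "OOB"]
  out
}

#' Univariate Cox survival filter
#'
#' One continuous-expression Cox model per candidate gene; genes with Wald
#' p < `alpha_surv` are retained with their coefficient, hazard ratio and p.
#'
#' @param expr An [expression_matrix()].
#' @param clinical Clinical data.frame (sample_id, os_time, os_event).
#' @param genes Candidate gene ids (present in the matrix).
#' @param alpha_surv Significance level (default 0.05).
#' @return A `signature_model` list (pre-partition): data.frame `genes`
#'   with gene, beta, hr, p; plus alpha_surv.
#' @export
prognostic_filter <- function(expr, clinical, genes, alpha_surv = 0.05) {
  X <- .as_plain(expr)
  miss <- setdiff(genes, rownames(X))
  if (length(miss))
    stop("gene(s) absent from matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  i <- match(colnames(X), clinical$sample_id)
  if (any(is.na(i))) stop("clinical table lacks sample(s) in matrix", call. = FALSE)
  time <- clinical$os_time[i]; event <- clinical$os_event[i]
  rows <- lapply(genes, function(g) {
    fit <- tryCatch(cox_fit(time, event, setNames(data.frame(x = X[g, ]), g)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(gene = g, beta = fit$table$coef, hr = fit$table$hr,
               p = fit$table$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  keep <- tab[tab$p < alpha_surv, , drop = FALSE]
  if (is.null(keep) || nrow(keep) == 0)
    stop("no gene passes the survival filter; review alpha_surv", call. = FALSE)
  rownames(keep) <- NULL
  structure(list(genes = keep, alpha_surv = alpha_surv,
                 X = NULL, Y = NULL, scale_mean = NULL, scale_sd = NULL,
                 median = NULL),
            class = "signature_model")
}

#' Partition signature genes by the sign of the Cox coefficient
#'
#' X = genes with beta > 0 (risk side), Y = genes with beta < 0 (protective
#' side); a coefficient of exactly zero is an error.
#'
#' @param model A `signature_model` from [prognostic_filter()].
#' @return The model with X and Y filled in.
#' @export
partition_by_sign <- function(model) {
  stopifnot(inherits(model, "signature_model"))
  b <- model$genes$beta
  if (any(b == 0))
    stop("Cox coefficient exactly zero for: ",
         paste(model$genes$gene[b == 0], collapse = ", "), call. = FALSE)
  model$X <- model$genes$gene[b > 0]
  model$Y <- model$genes$gene[b < 0]
  model
}

#' Per-sample m6A score
#'
#' raw_j = sum over X of expression - sum over Y of expression;
#' score = (raw - mean) / sd with the mean and n-1 sd taken from the
#' training cohort (stored in the model); applying a trained model to a new
#' cohort reuses the stored parameters.
#'
#' @param expr An [expression_matrix()] containing every model gene.
#' @param model A partitioned `signature_model`.
#' @param refit Fit scale parameters on this cohort (training mode, default
#'   TRUE when the model has none).
#' @return List with `scores` (named numeric), `model` (with scale
#'   parameters stored).
#' @export
m6a_score <- function(expr, model, refit = is.null(model$scale_mean)) {
  stopifnot(inherits(model, "signature_model"))
  if (is.null(model$X) && is.null(model$Y))
    stop("model is not partitioned; call partition_by_sign() first", call. = FALSE)
  X <- .as_plain(expr)
  need <- c(model$X, model$Y)
  miss <- setdiff(need, rownames(X))
  if (length(miss))
    stop("matrix lacks signature gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sum_x <- if (length(model$X)) colSums(X[model$X, , drop = FALSE]) else 0
  sum_y <- if (length(model$Y)) colSums(X[model$Y, , drop = FALSE]) else 0
  raw <- sum_x - sum_y
  if (refit) {
    if (sd(raw) == 0) stop("raw scores are constant; cannot scale", call. = FALSE)
    model$scale_mean <- mean(raw)
    model$scale_sd <- sd(raw)
  }
  scores <- (raw - model$scale_mean) / model$scale_sd
  names(scores) <- colnames(X)
  list(scores = scores, model = model)
}

#' Split samples into high and low score groups at the median
#'
#' score > median -> "high"; score <= median -> "low" (ties to low). The
#' median is stored for application to new cohorts.
#'
#' @param scores Named numeric score vector (>= 2 samples).
#' @param cutoff Optional pre-computed median from a training cohort.
#' @return List with `group` (named "high"/"low"), `median`.
#' @export
median_split <- function(scores, cutoff = NULL) {
  if (length(scores) < 2) stop("need >= 2 samples", call. = FALSE)
  if (is.null(cutoff)) cutoff <- median(scores)
  grp <- ifelse(scores > cutoff, "high", "low")
  if (all(grp == "low"))
    warning("all samples fall in the low group (constant scores?)", call. = FALSE)
  list(group = setNames(grp, names(scores)), median = cutoff)
}

#' Derive the full m6A score signature from clusters to group labels
#'
#' Convenience chain: moderated-t DE between the two modification patterns,
#' DEG thresholds, random-forest importance selection, univariate Cox
#' filter, sign partition, scoring, median split.
#'
#' @param expr An [expression_matrix()].
#' @param cluster_labels Two-level labels, one per sample.
#' @param clinical Clinical data.frame.
#' @param adj_p_max,lfc_min DEG thresholds (defaults 0.05 and 0.5).
#' @param n_trees Random-forest trees (default 500).
#' @param alpha_surv Survival-filter level (default 0.05).
#' @param seed Integer seed (random forest).
#' @param keep_rule Random-forest keep rule.
#' @return List with de, degs, rf, model, scores, group, median.
#' @export
derive_signature <- function(expr, cluster_labels, clinical,
                             adj_p_max = 0.05, lfc_min = 0.5,
                             n_trees = 500L, alpha_surv = 0.05, seed = 1L,
                             keep_rule = "positive_importance") {
  de <- moderated_t_de(expr, cluster_labels)
  degs <- filter_degs(de, adj_p_max, lfc_min)
  if (length(degs) < 2)
    stop("fewer than 2 genes pass the DEG thresholds", call. = FALSE)
  sub <- expression_matrix(.as_plain(expr)[degs, , drop = FALSE])
  rf <- rf_importance_select(sub, cluster_labels, n_trees = n_trees,
                             seed = seed, keep_rule = keep_rule)
  cand <- rf$gene[rf$kept]
  if (length(cand) == 0) stop("random forest kept no genes", call. = FALSE)
  model <- prognostic_filter(expr, clinical, cand, alpha_surv = alpha_surv)
  model <- partition_by_sign(model)
  sc <- m6a_score(expr, model)
  sp <- median_split(sc$scores)
  list(de = de, degs = degs, rf = rf, model = sc$model,
       scores = sc$scores, group = sp$group, median = sp$median)
}
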
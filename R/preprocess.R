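# Multi-cohort merging and empirical-Bayes location/scale batch adjustment
# (parametric, no reference batch, no biological covariates).

#' Merge expression matrices from several cohorts
#'
#' Genes are intersected across cohorts; the per-sample batch label is set to
#' the cohort name.
#'
#' @param matrices List of [expression_matrix()] objects (>= 2).
#' @param cohort_names Character vector, one name per matrix.
#' @return Merged [expression_matrix()] with batch labels.
#' @export
merge_cohorts <- function(matrices, cohort_names) {
  if (length(matrices) < 2) stop("need >= 2 cohorts to merge", call. = FALSE)
  if (length(cohort_names) != length(matrices))
    stop("one cohort name per matrix required", call. = FALSE)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (length(genes) == 0) stop("empty gene intersection across cohorts", call. = FALSE)
  all_samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_samples))
    stop("sample id(s) duplicated across cohorts: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  message(sprintf("merge_cohorts: keeping %d genes common to %d cohorts",
                  length(genes), length(matrices)))
  m <- do.call(cbind, lapply(matrices, function(x) .as_plain(x)[genes, , drop = FALSE]))
  batch <- rep(cohort_names, times = vapply(matrices, ncol, integer(1)))
  expression_matrix(m, batch = batch)
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric shrinkage of per-batch per-gene location and scale toward
#' pooled priors (Normal prior on location, inverse-gamma on scale, both with
#' method-of-moments hyperparameters), iterated to convergence and
#' back-transformed. With a single batch the input is returned unchanged.
#'
#' @param expr An [expression_matrix()].
#' @param batch Per-sample batch labels; defaults to the matrix's own batch
#'   attribute.
#' @param tol Convergence tolerance on max absolute change of the posterior
#'   location/scale (default 1e-6).
#' @param max_iter Iteration cap (default 100; a non-converged fit warns).
#' @param eb Use empirical-Bayes shrinkage (default TRUE). With `eb = FALSE`
#'   the observed per-batch location and scale are removed exactly (no
#'   pooling across genes): batch gene means agree exactly afterwards, at
#'   the price of overfitting gene-level sampling noise.
#' @return List with `expr` (corrected matrix, same shape and dimnames) and
#'   `model` (per-gene grand coefficients, per-batch shrunk location/scale,
#'   hyperparameters, iterations, convergence flag).
#' @export
combat_adjust <- function(expr, batch = NULL, tol = 1e-6, max_iter = 100L,
                          eb = TRUE) {
  if (is.null(batch)) batch <- batch_labels(expr)
  if (is.null(batch)) stop("no batch labels supplied", call. = FALSE)
  X <- .as_plain(expr)
  if (length(batch) != ncol(X)) stop("one batch label per sample required", call. = FALSE)
  batch <- as.character(batch)
  levels_b <- unique(batch)
  if (length(levels_b) == 1)
    return(list(expr = expr, model = list(n_batches = 1L, converged = TRUE,
                                          iterations = 0L, note = "single batch: no-op")))
  nb <- table(factor(batch, levels = levels_b))
  if (any(nb < 2))
    stop("batch(es) with a single sample: ",
         paste(names(nb)[nb < 2], collapse = ", "), call. = FALSE)
  pooled_var <- apply(X, 1, var)
  if (any(pooled_var == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(X)[pooled_var == 0], collapse = ", "), call. = FALSE)

  n <- ncol(X)
  G <- nrow(X)
  B <- length(levels_b)
  idx <- lapply(levels_b, function(b) which(batch == b))
  nbv <- vapply(idx, length, integer(1))

  # grand location: sample-size weighted mean of batch means per gene
  batch_mean <- sapply(idx, function(j) rowMeans(X[, j, drop = FALSE]))  # G x B
  alpha_hat <- as.vector(batch_mean %*% (nbv / n))
  # pooled residual variance about the batch means (n denominator)
  resid <- X - batch_mean[, match(batch, levels_b), drop = FALSE]
  sigma2_hat <- rowSums(resid^2) / n
  Z <- (X - alpha_hat) / sqrt(sigma2_hat)

  gamma_hat <- sapply(idx, function(j) rowMeans(Z[, j, drop = FALSE]))          # G x B
  delta2_hat <- sapply(seq_len(B), function(b) {
    j <- idx[[b]]
    rowSums((Z[, j, drop = FALSE] - gamma_hat[, b])^2) / (nbv[b] - 1)
  })

  # method-of-moments hyperparameters per batch
  gamma_bar <- colMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 2, var)
  m_d <- colMeans(delta2_hat)
  v_d <- apply(delta2_hat, 2, var)
  lambda_ig <- (2 * v_d + m_d^2) / v_d            # inverse-gamma shape
  theta_ig <- (m_d * v_d + m_d^3) / v_d           # inverse-gamma scale

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iters <- 0L
  converged <- TRUE
  if (eb) for (it in seq_len(max_iter)) {
    converged <- FALSE
    iters <- it
    g_old <- gamma_star; d_old <- delta2_star
    for (b in seq_len(B)) {
      j <- idx[[b]]
      gamma_star[, b] <- (nbv[b] * tau2_bar[b] * gamma_hat[, b] +
                            delta2_star[, b] * gamma_bar[b]) /
        (nbv[b] * tau2_bar[b] + delta2_star[, b])
      ss <- rowSums((Z[, j, drop = FALSE] - gamma_star[, b])^2)
      delta2_star[, b] <- (theta_ig[b] + 0.5 * ss) /
        (nbv[b] / 2 + lambda_ig[b] - 1)
    }
    if (max(abs(gamma_star - g_old), abs(delta2_star - d_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EB batch adjustment did not converge in ", max_iter, " iterations",
            call. = FALSE)

  Zc <- Z
  for (b in seq_len(B)) {
    j <- idx[[b]]
    Zc[, j] <- (Z[, j, drop = FALSE] - gamma_star[, b]) / sqrt(delta2_star[, b])
  }
  Xc <- Zc * sqrt(sigma2_hat) + alpha_hat
  dimnames(Xc) <- dimnames(X)
  model <- list(
    n_batches = B, batches = levels_b,
    alpha_hat = setNames(alpha_hat, rownames(X)),
    sigma2_hat = setNames(sigma2_hat, rownames(X)),
    gamma_star = gamma_star, delta2_star = delta2_star,
    hyper = list(gamma_bar = gamma_bar, tau2_bar = tau2_bar,
                 lambda = lambda_ig, theta = theta_ig),
    eb = eb, iterations = iters, converged = converged)
  list(expr = expression_matrix(Xc, batch = batch), model = model)
}
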
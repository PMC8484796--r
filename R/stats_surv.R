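# Statistical back-end shared by every pipeline stage: Cox PH, Kaplan-Meier,
# log-rank, rank-sum, Fisher, BH adjustment, correlation and ROC/AUC.

#' Fit a Cox proportional-hazards model
#'
#' Wald confidence intervals and p-values per covariate, with Efron tie
#' handling by default.
#'
#' @param time Follow-up times (days).
#' @param event Event indicators (0/1).
#' @param covariates Numeric vector, matrix or data.frame of covariates
#'   (samples in rows).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List of class `cox_fit`: `table` (data.frame with coef, hr,
#'   ci_low, ci_high, p per covariate), `loglik`, `iterations`, `converged`,
#'   `ties`, and the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.vector(covariates) && is.numeric(covariates))
    covariates <- matrix(covariates, ncol = 1, dimnames = list(NULL, "x"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time))
    stop("covariates must have one row per sample", call. = FALSE)
  if (sum(event) < 1) stop("Cox fit requires at least one event", call. = FALSE)
  num <- vapply(covariates, is.numeric, logical(1))
  if (any(num)) {
    const <- vapply(covariates[num], function(v) var(v) == 0, logical(1))
    if (any(const))
      stop("constant covariate(s): ",
           paste(names(covariates[num])[const], collapse = ", "), call. = FALSE)
    if (any(!vapply(covariates[num], function(v) all(is.finite(v)), logical(1))))
      stop("non-finite covariate values", call. = FALSE)
  }
  dat <- data.frame(.time = time, .event = event, covariates, check.names = TRUE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(colnames(dat)[-(1:2)], collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  s <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(abs(beta) > 15))
    stop("Cox fit did not converge (possible monotone likelihood / separation)",
         call. = FALSE)
  tab <- data.frame(
    covariate = names(beta),
    coef = unname(beta),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta) - 1.96 * se),
    ci_high = exp(unname(beta) + 1.96 * se),
    se = unname(se),
    p = unname(2 * pnorm(-abs(beta / se))),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, loglik = fit$loglik[2], iterations = fit$iter,
                 converged = TRUE, ties = ties, fit = fit),
            class = "cox_fit")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @return Data frame with time, n_risk, n_event, survival.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty survival data", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             survival = sf$surv)
}

#' Log-rank test between survival groups
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List of class `test_result` with statistic (chi-square), df, p,
#'   method.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("log-rank test needs >= 2 non-empty groups", call. = FALSE)
  groups <- droplevels(groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd_$n) - 1
  p <- stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  structure(list(statistic = unname(sd_$chisq), df = df, p = p,
                 method = "logrank"), class = "test_result")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p when both samples are small and tie-free, otherwise the normal
#' approximation with tie and continuity correction (base R's convention).
#'
#' @param x,y Numeric vectors.
#' @return `test_result` list with statistic (W), p, method, and the
#'   median difference as effect summary.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty sample", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 method = "wilcoxon_rank_sum",
                 effect = median(x) - median(y)),
            class = "test_result")
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional two-sided p (sum of tables as or less probable than observed);
#' the effect summary is the sample odds ratio ad/bc.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return `test_result` list with p, odds_ratio, method.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  ft <- fisher.test(table)
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  structure(list(p = ft$p.value, odds_ratio = unname(or),
                 method = "fisher_exact"), class = "test_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Correlate a vector against the columns of a matrix
#'
#' @param x Numeric vector (length >= 3).
#' @param M Numeric matrix or data.frame, one named column per variable.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame with name, r, p; zero-variance columns are skipped with
#'   a warning.
#' @export
correlate <- function(x, M, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  M <- as.matrix(M)
  if (length(x) < 3) stop("need length >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(M)))
    stop("non-finite values", call. = FALSE)
  if (nrow(M) != length(x)) stop("M must have one row per element of x", call. = FALSE)
  nm <- colnames(M)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(M)))
  keep <- logical(ncol(M))
  r <- p <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    if (var(M[, j]) == 0 || var(x) == 0) {
      warning("zero-variance column skipped: ", nm[j], call. = FALSE)
      next
    }
    ct <- suppressWarnings(cor.test(x, M[, j], method = method))
    r[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
    keep[j] <- TRUE
  }
  data.frame(name = nm[keep], r = r[keep], p = p[keep], stringsAsFactors = FALSE)
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney U statistic divided by n1*n0 (ties counted 0.5);
#' the curve enumerates (FPR, TPR) at every distinct threshold.
#'
#' @param score Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical); both classes required.
#' @return List with `auc` and `curve` (data.frame threshold, fpr, tpr).
#' @export
roc_auc <- function(score, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(score) != length(labels)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  rk <- rank(score)                       # average ranks handle ties as 0.5
  auc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(score >= t & labels == 0) / n0, numeric(1)),
    tpr = vapply(thr, function(t) sum(score >= t & labels == 1) / n1, numeric(1))
  )
  list(auc = auc, curve = curve)
}
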
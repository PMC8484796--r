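# Deterministic synthetic-cohort generator. Emulates the statistical
# structure the analysis assumes: two latent expression clusters over the
# m6A regulator panel, cohort batch effects, proportional-hazards survival
# linked to cluster membership, per-cluster activation of signature gene
# sets, and per-gene mutation frequencies.

# One global seed expands to fixed per-component substreams so each piece of
# randomness is reproducible independently of the others.
.sub_seed <- function(seed, offset) (as.integer(seed) + 1000L * offset) %% 2147483647L

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: two equally
#' likely latent clusters separated by 2 SD on the 21-gene regulator panel,
#' two cohorts with modest location/scale batch effects, exponential survival
#' with a cluster hazard ratio of 2 and 30% censoring, and a handful of
#' activated signature gene sets.
#'
#' @param n_per_cohort Integer vector, samples per cohort.
#' @param cohorts Cohort names (batch labels).
#' @param regulator_panel Gene ids of the regulator panel (default the
#'   package's 21 m6A regulators).
#' @param n_background_genes Number of uninformative N(0,1) genes.
#' @param cluster_prop Probability a sample belongs to cluster 2 ("B").
#' @param cluster_effect Mean shift (in SD units) on regulator genes for
#'   cluster 2.
#' @param batch_shift Per-cohort additive offsets (recycled).
#' @param batch_scale Per-cohort variance multipliers (recycled).
#' @param signature_sets Named list of lists `list(genes=..., shift=...)`:
#'   genes shifted by `shift` in cluster 2. Defaults to 3 sets of 15 genes
#'   carved from the background with shifts (1, -1, 0.8).
#' @param baseline_hazard Exponential baseline hazard (per day).
#' @param beta_cluster Planted log hazard ratio of cluster 2 vs 1.
#' @param censor_rate Target censoring fraction in \[0, 1).
#' @param mutation_freqs Named per-gene mutation probability, either a single
#'   vector or a list with per-cluster vectors `list(A=..., B=...)`.
#' @param p_gain,p_loss Per-gene CNV gain/loss probabilities.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_cohort = c(100, 100),
                       cohorts = paste0("cohort", seq_along(n_per_cohort)),
                       regulator_panel = NULL,
                       n_background_genes = 300,
                       cluster_prop = 0.5,
                       cluster_effect = 2,
                       batch_shift = c(0, 1.5),
                       batch_scale = c(1, 1.6),
                       signature_sets = NULL,
                       baseline_hazard = 0.001,
                       beta_cluster = log(2),
                       censor_rate = 0.3,
                       mutation_freqs = NULL,
                       p_gain = 0.15,
                       p_loss = 0.2,
                       seed = 1L) {
  if (is.null(regulator_panel))
    regulator_panel <- m6a_regulators()$gene_id
  stopifnot(length(n_per_cohort) == length(cohorts))
  if (cluster_prop <= 0 || cluster_prop >= 1)
    stop("cluster_prop must be in (0,1)", call. = FALSE)
  if (cluster_effect < 0) stop("cluster_effect must be >= 0", call. = FALSE)
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  n <- sum(n_per_cohort)
  if (min(cluster_prop, 1 - cluster_prop) * n < 2)
    stop("degenerate cluster: cluster_prop * n < 2", call. = FALSE)
  if (is.null(signature_sets)) {
    bg <- paste0("BG", seq_len(n_background_genes))
    k <- min(15, max(2, n_background_genes %/% 20))
    signature_sets <- list(
      SIG_UP    = list(genes = bg[seq_len(k)], shift = 1),
      SIG_DOWN  = list(genes = bg[k + seq_len(k)], shift = -1),
      SIG_MILD  = list(genes = bg[2 * k + seq_len(k)], shift = 0.8)
    )
  }
  if (is.null(mutation_freqs)) {
    mutation_freqs <- list(
      A = setNames(rep(0.05, length(regulator_panel)), regulator_panel),
      B = setNames(rep(0.12, length(regulator_panel)), regulator_panel)
    )
  }
  fr <- unlist(mutation_freqs)
  if (any(fr < 0 | fr > 1)) stop("mutation frequencies must be in [0,1]", call. = FALSE)
  structure(list(
    n_per_cohort = as.integer(n_per_cohort), cohorts = cohorts,
    regulator_panel = regulator_panel, n_background_genes = as.integer(n_background_genes),
    cluster_prop = cluster_prop, cluster_effect = cluster_effect,
    batch_shift = rep_len(batch_shift, length(cohorts)),
    batch_scale = rep_len(batch_scale, length(cohorts)),
    signature_sets = signature_sets, baseline_hazard = baseline_hazard,
    beta_cluster = beta_cluster, censor_rate = censor_rate,
    mutation_freqs = mutation_freqs, p_gain = p_gain, p_loss = p_loss,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate survival times under an exponential proportional-hazards model
#'
#' Event times are Exponential(lambda * exp(lp)). Censoring is
#' administrative-uniform on \[0, c_max\], with c_max solved numerically so
#' the expected censoring fraction equals `censor_rate`.
#'
#' @param linear_predictor Per-sample log relative hazard.
#' @param lambda Baseline hazard (> 0).
#' @param censor_rate Target censoring fraction in \[0, 1).
#' @param seed Integer seed.
#' @return Data frame with os_time, os_event.
#' @export
simulate_survival <- function(linear_predictor, lambda, censor_rate = 0, seed = 1L) {
  if (!all(is.finite(linear_predictor)))
    stop("non-finite linear predictor", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  n <- length(linear_predictor)
  rates <- lambda * exp(linear_predictor)
  set.seed(.sub_seed(seed, 2L))
  t_event <- rexp(n, rate = rates)
  if (censor_rate == 0)
    return(data.frame(os_time = t_event, os_event = rep(1L, n)))
  # P(censored | C ~ U(0, cmax)) = mean_i (1 - exp(-r_i cmax)) / (r_i cmax)
  cens_frac <- function(cmax) mean((1 - exp(-rates * cmax)) / (rates * cmax))
  # cens_frac decreases from 1 (cmax -> 0) to 0 (cmax -> Inf)
  upper <- 1 / min(rates)
  while (cens_frac(upper) > censor_rate) upper <- upper * 2
  cmax <- uniroot(function(cm) cens_frac(cm) - censor_rate,
                  lower = 1e-8, upper = upper, tol = 1e-10)$root
  t_cens <- runif(n, 0, cmax)
  data.frame(os_time = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens))
}

#' Simulate a somatic mutation table
#'
#' Independent Bernoulli draw per (gene, sample); variant classifications are
#' sampled uniformly from the controlled vocabulary unless `class_probs`
#' supplies a named probability vector.
#'
#' @param freqs Named gene -> probability vector.
#' @param samples Sample ids.
#' @param seed Integer seed.
#' @param panel Optional known gene panel; genes in `freqs` missing from it
#'   trigger a warning but are still simulated.
#' @param class_probs Optional named probabilities over
#'   [MUTATION_CLASSES].
#' @return A [mutation_table()].
#' @export
simulate_mutations <- function(freqs, samples, seed = 1L, panel = NULL,
                               class_probs = NULL) {
  if (any(freqs < 0 | freqs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (!is.null(panel)) {
    unk <- setdiff(names(freqs), panel)
    if (length(unk))
      warning("gene(s) absent from panel, still simulated: ",
              paste(unk, collapse = ", "), call. = FALSE)
  }
  set.seed(.sub_seed(seed, 3L))
  recs <- list()
  cls <- MUTATION_CLASSES
  pr <- if (is.null(class_probs)) rep(1 / length(cls), length(cls)) else class_probs[cls]
  for (g in names(freqs)) {
    hit <- runif(length(samples)) < freqs[[g]]
    if (any(hit)) {
      recs[[g]] <- data.frame(
        sample_id = samples[hit], gene_id = g,
        variant_classification = sample(cls, sum(hit), replace = TRUE, prob = pr),
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0)
    return(mutation_table(data.frame(sample_id = character(), gene_id = character(),
                                     variant_classification = character(),
                                     stringsAsFactors = FALSE)))
  mutation_table(do.call(rbind, c(recs, list(make.row.names = FALSE))))
}

#' Simulate a full synthetic cohort
#'
#' Draws cluster labels, regulator/background/signature expression, applies
#' per-cohort location/scale batch effects, simulates proportional-hazards
#' survival tied to cluster membership, and mutation / CNV calls. Identical
#' config (including seed) gives identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_cohort`: expr ([expression_matrix()]),
#'   clinical (data.frame), mutations, cnv, and `truth` (cluster labels,
#'   informative-gene flags, batch parameters, planted betas).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n <- sum(cf$n_per_cohort)
  cohort <- rep(cf$cohorts, times = cf$n_per_cohort)
  sample_ids <- sprintf("%s_S%03d", cohort, unlist(lapply(cf$n_per_cohort, seq_len)))

  set.seed(.sub_seed(cf$seed, 1L))
  cluster <- 1L + as.integer(runif(n) < cf$cluster_prop)   # 2 = shifted cluster "B"

  genes <- c(cf$regulator_panel, paste0("BG", seq_len(cf$n_background_genes)))
  p <- length(genes)
  X <- matrix(rnorm(p * n), nrow = p, dimnames = list(genes, sample_ids))
  reg_idx <- seq_along(cf$regulator_panel)
  X[reg_idx, cluster == 2L] <- X[reg_idx, cluster == 2L] + cf$cluster_effect
  informative <- setNames(logical(p), genes)
  informative[reg_idx] <- cf$cluster_effect > 0
  for (s in cf$signature_sets) {
    gs <- intersect(s$genes, genes)
    X[gs, cluster == 2L] <- X[gs, cluster == 2L] + s$shift
    informative[gs] <- informative[gs] | s$shift != 0
  }
  # per-cohort location/scale batch effect
  for (i in seq_along(cf$cohorts)) {
    j <- cohort == cf$cohorts[i]
    X[, j] <- X[, j] * sqrt(cf$batch_scale[i]) + cf$batch_shift[i]
  }

  surv <- simulate_survival(cf$beta_cluster * (cluster == 2L),
                            lambda = cf$baseline_hazard,
                            censor_rate = cf$censor_rate,
                            seed = .sub_seed(cf$seed, 10L))
  clinical <- data.frame(sample_id = sample_ids,
                         os_time = surv$os_time, os_event = surv$os_event,
                         cohort = cohort, stringsAsFactors = FALSE)

  fr <- cf$mutation_freqs
  if (is.list(fr) && !is.null(fr$A)) {
    mutA <- simulate_mutations(fr$A, sample_ids[cluster == 1L],
                               seed = .sub_seed(cf$seed, 20L), panel = genes)
    mutB <- simulate_mutations(fr$B, sample_ids[cluster == 2L],
                               seed = .sub_seed(cf$seed, 21L), panel = genes)
    mutations <- mutation_table(rbind(mutA, mutB))
  } else {
    mutations <- simulate_mutations(fr, sample_ids,
                                    seed = .sub_seed(cf$seed, 20L), panel = genes)
  }

  set.seed(.sub_seed(cf$seed, 30L))
  reg <- cf$regulator_panel
  calls <- apply(rmultinom(length(reg) * n, 1,
                           c(cf$p_loss, 1 - cf$p_gain - cf$p_loss, cf$p_gain)),
                 2, which.max)
  cnv <- cnv_table(data.frame(
    sample_id = rep(sample_ids, times = length(reg)),
    gene_id = rep(reg, each = n),
    call = c("loss", "neutral", "gain")[calls],
    stringsAsFactors = FALSE))

  structure(list(
    expr = expression_matrix(X, batch = cohort),
    clinical = clinical,
    mutations = mutations,
    cnv = cnv,
    truth = list(cluster = setNames(cluster, sample_ids),
                 informative = informative,
                 batch = data.frame(cohort = cf$cohorts, shift = cf$batch_shift,
                                    scale = cf$batch_scale),
                 beta_cluster = cf$beta_cluster,
                 config = cf)), class = "synthetic_cohort")
}
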
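# Configuration-driven orchestration: simulate or load inputs, merge and
# batch-correct, landscape summaries, consensus clustering, optional
# enrichment, signature derivation, scoring and survival comparison.
# Every stage writes TSV; the run manifest records parameters, seed and
# per-file checksums so a rerun with the same config is byte-identical.

#' Build a pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `inputs` (a list of
#' file paths: `expression` = named vector per cohort, `clinical`, optional
#' `gmt`, `maf`, `cnv`) must be given. Defaults mirror the analysis'
#' standard thresholds: 1000 clustering repetitions, Euclidean distance,
#' DEG cut at adjusted p < 0.05 and |log2FC| > 0.5, survival filter at
#' p < 0.05, median split.
#'
#' @param simulation Optional [sim_config()].
#' @param inputs Optional list of input paths.
#' @param out_dir Output directory.
#' @param seed Integer seed (mandatory).
#' @param k_range,reps,subsample Consensus-clustering parameters.
#' @param adj_p_max,lfc_min DEG thresholds.
#' @param alpha_surv Survival-filter level.
#' @param n_trees Random-forest trees.
#' @param regulators Regulator panel gene ids (default: packaged 21-gene
#'   panel).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL, out_dir,
                            seed, k_range = 2:4, reps = 1000L, subsample = 0.8,
                            adj_p_max = 0.05, lfc_min = 0.5, alpha_surv = 0.05,
                            n_trees = 500L, regulators = NULL) {
  if (is.null(simulation) == is.null(inputs))
    stop("exactly one of simulation / inputs must be supplied", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(regulators)) regulators <- m6a_regulators()$gene_id
  structure(list(simulation = simulation, inputs = inputs, out_dir = out_dir,
                 seed = as.integer(seed), k_range = k_range,
                 reps = as.integer(reps), subsample = subsample,
                 adj_p_max = adj_p_max, lfc_min = lfc_min,
                 alpha_surv = alpha_surv, n_trees = as.integer(n_trees),
                 regulators = regulators),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]; a `simulation:` block is passed to
#' [sim_config()].
#'
#' @param path YAML file path.
#' @param out_dir Optional output-directory override.
#' @param seed Optional seed override.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    sim_args <- y$simulation
    if (!is.null(seed)) sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
  }
  args <- y[setdiff(names(y), "simulation")]
  args$simulation <- sim
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(seed)) args$seed <- seed
  do.call(pipeline_config, args)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: simulate/load -> merge + batch-correct -> regulator landscape ->
#' consensus clustering of the regulator panel -> cluster naming by survival
#' -> signature derivation (DE, random forest, Cox filter, score, median
#' split) -> survival comparison of score groups. Each stage writes TSV
#' outputs under `config$out_dir`; `manifest.json` records parameters, the
#' seed and an md5 checksum per output file.
#'
#' @param config A `pipeline_config`.
#' @return Invisible list with the in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines("incomplete", file.path(config$out_dir, "INCOMPLETE"))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulation)) {
    cohort <- stage("simulate", simulate_cohort(config$simulation))
    expr <- cohort$expr; clinical <- cohort$clinical
    mutations <- cohort$mutations; cnv <- cohort$cnv
  } else {
    inp <- config$inputs
    mats <- lapply(inp$expression, read_expression)
    if (length(mats) > 1) {
      expr <- stage("merge", merge_cohorts(mats, names(inp$expression)))
    } else {
      expr <- mats[[1]]
    }
    clinical <- stage("clinical", read_clinical(inp$clinical))
    mutations <- if (!is.null(inp$maf)) read_maf(inp$maf) else NULL
    cnv <- if (!is.null(inp$cnv)) read_cnv(inp$cnv) else NULL
    cohort <- NULL
  }

  # --- batch correction ---------------------------------------------------
  b <- batch_labels(expr)
  if (!is.null(b) && length(unique(b)) > 1) {
    adj <- stage("combat", combat_adjust(expr))
    expr <- adj$expr
  }
  al <- stage("align", align_samples(expr, clinical, mutations))
  expr <- al$expr; clinical <- al$clinical; mutations <- al$mutations
  outputs <- c(outputs, .write_tsv(
    data.frame(gene_id = rownames(expr), .as_plain(expr), check.names = FALSE),
    file.path(config$out_dir, "expression_corrected.tsv")))

  # --- landscape ----------------------------------------------------------
  reg <- intersect(config$regulators, rownames(expr))
  if (length(reg) < 2) stop("fewer than 2 regulator genes in the matrix", call. = FALSE)
  if (!is.null(mutations) && nrow(mutations) > 0) {
    mf <- stage("landscape", mutation_frequencies(mutations, clinical$sample_id, reg))
    outputs <- c(outputs, .write_tsv(mf$per_gene,
                                     file.path(config$out_dir, "mutation_freq.tsv")))
  }
  if (!is.null(cnv) && nrow(cnv) > 0) {
    outputs <- c(outputs, .write_tsv(cnv_frequencies(cnv),
                                     file.path(config$out_dir, "cnv_freq.tsv")))
  }

  # --- consensus clustering on the regulator panel ------------------------
  reg_expr <- expression_matrix(.as_plain(expr)[reg, , drop = FALSE])
  cc <- stage("cluster", consensus_cluster(reg_expr, k_range = config$k_range,
                                           reps = config$reps,
                                           subsample = config$subsample,
                                           seed = config$seed))
  sel <- select_k(cc)
  labels <- cc$labels[[as.character(sel$k)]]
  named <- if (sel$k == 2) name_clusters(labels, clinical)
           else setNames(LETTERS[labels], names(labels))
  outputs <- c(outputs, .write_tsv(
    data.frame(sample_id = names(named), cluster = unname(named)),
    file.path(config$out_dir, "labels.tsv")))
  pca <- pca_embed(reg_expr, 2)
  outputs <- c(outputs, .write_tsv(
    data.frame(sample_id = rownames(pca$coords), pca$coords),
    file.path(config$out_dir, "pca.tsv")))

  # --- cluster survival ---------------------------------------------------
  lr_cluster <- logrank_test(clinical$os_time, clinical$os_event,
                             named[clinical$sample_id])
  # --- signature ----------------------------------------------------------
  sig <- stage("signature", derive_signature(
    expr, named[colnames(expr)], clinical,
    adj_p_max = config$adj_p_max, lfc_min = config$lfc_min,
    n_trees = config$n_trees, alpha_surv = config$alpha_surv,
    seed = config$seed))
  outputs <- c(outputs, .write_tsv(sig$de, file.path(config$out_dir, "degs.tsv")))
  outputs <- c(outputs, .write_tsv(sig$rf,
                                   file.path(config$out_dir, "rf_importance.tsv")))
  outputs <- c(outputs, .write_tsv(
    data.frame(sample_id = names(sig$scores), m6a_score = unname(sig$scores),
               group = unname(sig$group[names(sig$scores)])),
    file.path(config$out_dir, "scores.tsv")))
  model_json <- file.path(config$out_dir, "signature_model.json")
  jsonlite::write_json(list(X = sig$model$X, Y = sig$model$Y,
                            genes = sig$model$genes,
                            scale_mean = sig$model$scale_mean,
                            scale_sd = sig$model$scale_sd,
                            median = sig$median),
                       model_json, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, model_json)

  # --- score-group survival -----------------------------------------------
  grp <- sig$group[clinical$sample_id]
  lr_score <- logrank_test(clinical$os_time, clinical$os_event, grp)
  cx <- cox_fit(clinical$os_time, clinical$os_event,
                data.frame(high = as.integer(grp == "high")))
  km_tab <- do.call(rbind, lapply(c("high", "low"), function(g) {
    km <- km_estimate(clinical$os_time[grp == g], clinical$os_event[grp == g])
    cbind(group = g, km)
  }))
  outputs <- c(outputs, .write_tsv(km_tab,
                                   file.path(config$out_dir, "km_highlow.tsv")))
  stats <- data.frame(
    quantity = c("logrank_p_clusters", "logrank_p_score_groups",
                 "cox_hr_high_vs_low", "selected_k"),
    value = c(lr_cluster$p, lr_score$p, cx$table$hr, sel$k))
  outputs <- c(outputs, .write_tsv(stats,
                                   file.path(config$out_dir, "summary_stats.tsv")))

  # --- manifest -----------------------------------------------------------
  sums <- tools::md5sum(sort(outputs))
  manifest <- list(
    package = "m6ascape",
    seed = config$seed,
    parameters = list(k_range = config$k_range, reps = config$reps,
                      subsample = config$subsample, adj_p_max = config$adj_p_max,
                      lfc_min = config$lfc_min, alpha_surv = config$alpha_surv,
                      n_trees = config$n_trees),
    simulated = !is.null(config$simulation),
    n_samples = ncol(expr), n_genes = nrow(expr),
    selected_k = sel$k,
    checksums = as.list(setNames(unname(sums), basename(names(sums)))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  unlink(file.path(config$out_dir, "INCOMPLETE"))
  invisible(list(expr = expr, clinical = clinical, clusters = named,
                 consensus = cc, selected_k = sel, signature = sig,
                 logrank_clusters = lr_cluster, logrank_score = lr_score,
                 cox_score = cx, manifest = manifest, cohort = cohort))
}
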
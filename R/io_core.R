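#' @importFrom stats median p.adjust pnorm pt qnorm rbinom rexp rnorm
#'   runif sd var cor cor.test fisher.test wilcox.test phyper prcomp hclust
#'   cutree dist as.dist uniroot setNames quantile rmultinom
#' @importFrom utils read.delim write.table head modifyList
NULL

# Controlled vocabulary for somatic variant classifications.
MUTATION_CLASSES <- c(
  "missense", "nonsense", "frame_shift_del", "frame_shift_ins",
  "in_frame_del", "in_frame_ins", "splice_site", "multi_hit", "other"
)

# Standard MAF Variant_Classification terms mapped onto the vocabulary.
.MAF_CLASS_MAP <- c(
  missense_mutation = "missense",
  nonsense_mutation = "nonsense",
  frame_shift_del   = "frame_shift_del",
  frame_shift_ins   = "frame_shift_ins",
  in_frame_del      = "in_frame_del",
  in_frame_ins      = "in_frame_ins",
  splice_site       = "splice_site",
  multi_hit         = "multi_hit",
  nonstop_mutation  = "nonsense",
  translation_start_site = "other"
)

#' Construct a validated expression matrix
#'
#' The expression container used throughout the package: a numeric genes x
#' samples matrix (log2 scale expected) with unique gene and sample ids and an
#' optional per-sample batch label stored as an attribute.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param batch Optional character vector of per-sample batch/cohort labels,
#'   length `ncol(values)`.
#' @return A numeric matrix of class `expr_matrix` with a `batch` attribute.
#' @export
expression_matrix <- function(values, batch = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s' (missing values are not imputed)",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]), call. = FALSE)
  }
  if (!is.null(batch)) {
    if (length(batch) != ncol(values))
      stop("batch labels must have one entry per sample", call. = FALSE)
    batch <- as.character(batch)
    names(batch) <- colnames(values)
  }
  structure(values, batch = batch, class = c("expr_matrix", class(values)))
}

#' Per-sample batch labels of an expression matrix
#' @param expr An `expr_matrix`.
#' @return Named character vector of batch labels, or NULL.
#' @export
batch_labels <- function(expr) attr(expr, "batch")

# Drop the expr_matrix class/attrs for plain-matrix math.
.as_plain <- function(expr) {
  m <- unclass(expr)
  attr(m, "batch") <- NULL
  m
}

#' Read a gene x sample expression matrix
#'
#' Reads either a plain TSV (header row of sample ids, first column gene ids)
#' or a GCT 1.2 file (two header lines, then dimensions, then Name /
#' Description columns before the data).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`.
#' @param log2_offset If `TRUE`, apply `log2(x + 1)` on load (for raw counts
#'   or TPM); default `FALSE`, values are assumed already log2-scale.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "gct"), log2_offset = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed expression TSV header in ", path, call. = FALSE)
    gene_ids <- as.character(df[[1]])
    dat <- df[, -1, drop = FALSE]
  } else {
    lines <- readLines(path)
    if (length(lines) < 3 || !grepl("^#1\\.2", lines[1]))
      stop("malformed GCT header (expected '#1.2' on line 1) in ", path, call. = FALSE)
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]][1:2]))
    if (any(is.na(dims))) stop("malformed GCT dimension line in ", path, call. = FALSE)
    df <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"), header = TRUE,
                     sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) != dims[1] || (ncol(df) - 2L) != dims[2])
      stop(sprintf("GCT declares %d genes x %d samples but file has %d x %d",
                   dims[1], dims[2], nrow(df), ncol(df) - 2L), call. = FALSE)
    gene_ids <- as.character(df[[1]])
    dat <- df[, -(1:2), drop = FALSE]
  }
  for (j in seq_along(dat)) {
    v <- dat[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) {
        i <- which(is.na(vn) & !is.na(v))[1]
        stop(sprintf("non-numeric expression value '%s' at gene '%s', column '%s'",
                     v[i], gene_ids[i], colnames(dat)[j]), call. = FALSE)
      }
      dat[[j]] <- vn
    }
  }
  m <- as.matrix(dat)
  rownames(m) <- gene_ids
  if (log2_offset) m <- log2(m + 1)
  expression_matrix(m)
}

#' Write an expression matrix as TSV
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), .as_plain(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `name<TAB>description<TAB>gene<TAB>gene...`. Gene order
#' within a set is preserved; duplicated genes within a line are dropped with
#' a warning.
#'
#' @param path File path.
#' @return Named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d fields (need >= 3)", i, length(f)), call. = FALSE)
    nm[i] <- f[1]
    desc[i] <- f[2]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicated gene ids deduplicated", f[1]), call. = FALSE)
      genes <- unique(genes)
    }
    if (length(genes) == 0)
      stop(sprintf("GMT set '%s' (line %d) is empty", f[1], i), call. = FALSE)
    sets[[i]] <- genes
  }
  if (anyDuplicated(nm))
    stop("duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(sets) <- nm
  attr(sets, "description") <- setNames(desc, nm)
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with mandatory columns `sample_id`, `os_time` (days, non-negative) and
#' `os_event` (0/1). All other columns are preserved verbatim as covariates /
#' extras (e.g. sex, age, stage, cohort, tide_score, ic50_* columns).
#'
#' @param path File path.
#' @return A `data.frame` with validated survival columns.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate a clinical data.frame
#' @param df Data frame with sample_id, os_time, os_event columns.
#' @return The validated data frame.
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clinical table lacks mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0))
    stop("os_time must be finite and >= 0", call. = FALSE)
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1", call. = FALSE)
  df
}

#' Read a mutation table from a MAF-dialect file
#'
#' Requires (case-insensitively) the columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification`; all other MAF columns
#' are ignored. Standard MAF classification terms are mapped onto the
#' package's controlled vocabulary; unmapped terms become `"other"` with a
#' warning.
#'
#' @param path File path.
#' @return A `data.frame` with columns sample_id, gene_id,
#'   variant_classification.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  lc <- tolower(colnames(df))
  need <- c("hugo_symbol", "tumor_sample_barcode", "variant_classification")
  miss <- setdiff(need, lc)
  if (length(miss))
    stop("MAF lacks mandatory column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  gene <- as.character(df[[which(lc == "hugo_symbol")[1]]])
  samp <- as.character(df[[which(lc == "tumor_sample_barcode")[1]]])
  rawcl <- as.character(df[[which(lc == "variant_classification")[1]]])
  key <- tolower(rawcl)
  cl <- unname(.MAF_CLASS_MAP[key])
  if (any(is.na(cl))) {
    unk <- unique(rawcl[is.na(cl)])
    warning("unmapped Variant_Classification term(s) set to 'other': ",
            paste(unk, collapse = ", "), call. = FALSE)
    cl[is.na(cl)] <- "other"
  }
  mutation_table(data.frame(sample_id = samp, gene_id = gene,
                            variant_classification = cl,
                            stringsAsFactors = FALSE))
}

#' Construct/validate a mutation table
#' @param records Data frame with sample_id, gene_id, variant_classification.
#' @return The validated data frame.
#' @export
mutation_table <- function(records) {
  need <- c("sample_id", "gene_id", "variant_classification")
  miss <- setdiff(need, colnames(records))
  if (length(miss))
    stop("mutation table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(records$variant_classification), MUTATION_CLASSES)
  if (length(bad))
    stop("variant_classification outside controlled vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  records
}

#' Write a mutation table as a minimal MAF
#' @param mut Mutation table.
#' @param path Output path.
#' @export
write_maf <- function(mut, path) {
  inv <- setNames(names(.MAF_CLASS_MAP), .MAF_CLASS_MAP)
  # title-case canonical MAF spellings for round-trip
  canon <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
             frame_shift_del = "Frame_Shift_Del", frame_shift_ins = "Frame_Shift_Ins",
             in_frame_del = "In_Frame_Del", in_frame_ins = "In_Frame_Ins",
             splice_site = "Splice_Site", multi_hit = "Multi_Hit", other = "Other")
  df <- data.frame(Hugo_Symbol = mut$gene_id,
                   Tumor_Sample_Barcode = mut$sample_id,
                   Variant_Classification = unname(canon[mut$variant_classification]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct/validate a CNV call table
#'
#' One call per (sample, gene) from the 3-level vocabulary loss / neutral /
#' gain.
#'
#' @param records Data frame with sample_id, gene_id, call.
#' @return The validated data frame.
#' @export
cnv_table <- function(records) {
  need <- c("sample_id", "gene_id", "call")
  miss <- setdiff(need, colnames(records))
  if (length(miss))
    stop("CNV table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(records$call), c("loss", "neutral", "gain"))
  if (length(bad))
    stop("CNV call outside {loss, neutral, gain}: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(records[, c("sample_id", "gene_id")]))
    stop("duplicate (sample, gene) CNV calls", call. = FALSE)
  records
}

#' Read a CNV call table (TSV with sample_id, gene_id, call)
#' @param path File path.
#' @return Validated CNV table.
#' @export
read_cnv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cnv_table(read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
}

#' Harmonize sample ids across expression, clinical and mutation inputs
#'
#' Takes the intersection of sample ids, reports dropped ids, and reorders
#' everything to expression-matrix order.
#'
#' @param expr An `expr_matrix`.
#' @param clinical Clinical data.frame.
#' @param mutations Optional mutation table (records for samples outside the
#'   intersection are dropped, not an error: mutation calls routinely cover a
#'   sample subset).
#' @return List with elements expr, clinical, mutations, dropped.
#' @export
align_samples <- function(expr, clinical, mutations = NULL) {
  keep <- intersect(colnames(expr), clinical$sample_id)
  if (length(keep) == 0) stop("no samples shared by expression and clinical", call. = FALSE)
  dropped <- list(expression = setdiff(colnames(expr), keep),
                  clinical = setdiff(clinical$sample_id, keep))
  n_drop <- length(dropped$expression) + length(dropped$clinical)
  if (n_drop > 0)
    message(sprintf("align_samples: dropped %d expression and %d clinical sample id(s) outside the intersection",
                    length(dropped$expression), length(dropped$clinical)))
  b <- batch_labels(expr)
  expr2 <- expression_matrix(.as_plain(expr)[, keep, drop = FALSE],
                             batch = if (!is.null(b)) b[keep] else NULL)
  clin2 <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  mut2 <- if (!is.null(mutations)) mutations[mutations$sample_id %in% keep, , drop = FALSE] else NULL
  list(expr = expr2, clinical = clin2, mutations = mut2, dropped = dropped)
}

#' The 21-gene m6A regulator panel with writer/eraser/reader categories
#'
#' @return Data frame with columns gene_id and category.
#' @export
m6a_regulators <- function() {
  path <- system.file("extdata", "m6a_regulators.tsv", package = "m6ascape")
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
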
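#' Read an expression matrix from TSV
#'
#' Tab-separated file, first column gene ids, header row of sample ids.
#' Duplicate gene rows are collapsed by their arithmetic mean with a warning.
#'
#' @param path Path to the TSV file.
#' @param is_log2 Set if values are log2-transformed; default linear scale.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, is_log2 = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed expression file: ", path)
  genes <- trimws(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing expression value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("collapsed %d duplicated gene id(s) by mean: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(num) <- genes
  colnames(num) <- trimws(colnames(num))
  expression_matrix(num, is_log2 = is_log2)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; round-trips values exactly (full
#' precision via `format(..., digits = 17)`).
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = rownames(expr),
                   format(unclass(expr), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("gene", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert MAF-format mutation calls to a binary mutation matrix
#'
#' A sample is called mutated in a gene when it carries at least
#' `min_mutations` variants in that gene after dropping the
#' `excluded_classes` variant classifications. The default excludes Silent
#' variants; this is a configurable choice, not a claim about any
#' particular upstream pipeline.
#'
#' @param path Tab-separated MAF with at least `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification` columns.
#' @param min_mutations Minimum qualifying variant count per gene/sample.
#' @param excluded_classes Variant classifications to ignore.
#' @param samples Optional character vector declaring the full sample set
#'   (so samples with no qualifying variants still appear as columns).
#' @return A [mutation_matrix()].
#' @export
read_maf <- function(path, min_mutations = 1L,
                     excluded_classes = "Silent", samples = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MAF missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$Hugo_Symbol <- trimws(df$Hugo_Symbol)
  df$Tumor_Sample_Barcode <- trimws(df$Tumor_Sample_Barcode)
  all_samples <- unique(c(df$Tumor_Sample_Barcode, trimws(samples)))
  keep <- !(df$Variant_Classification %in% excluded_classes)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no qualifying variants in MAF; returning 0-gene matrix")
    status <- matrix(integer(0), nrow = 0, ncol = length(all_samples),
                     dimnames = list(character(0), all_samples))
    return(mutation_matrix(status))
  }
  counts <- table(gene = df$Hugo_Symbol, sample = df$Tumor_Sample_Barcode)
  status <- matrix(0L, nrow = nrow(counts), ncol = length(all_samples),
                   dimnames = list(rownames(counts), all_samples))
  status[, colnames(counts)] <- (unclass(counts) >= min_mutations) + 0L
  mutation_matrix(status)
}

#' Read a binary mutation matrix from TSV
#'
#' Alternative to [read_maf()] when statuses are precomputed: first column
#' gene id, header row sample ids, cells 0/1.
#'
#' @param path Path to the TSV file.
#' @return A [mutation_matrix()].
#' @export
read_mutation_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed mutation file: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- trimws(as.character(df[[1L]]))
  colnames(m) <- trimws(colnames(m))
  mutation_matrix(m)
}

#' Read a clinical table from TSV
#'
#' Mandatory columns `sample_id`, `time`, `event`; optional `subtype`,
#' `purity`, and any number of immune abundance columns prefixed `abund_`.
#'
#' @param path Path to the TSV file.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  clinical_table(df)
}

#' Write a cohort to three TSV files
#'
#' @param ch A [cohort()].
#' @param prefix Path prefix; writes `<prefix>_expression.tsv`,
#'   `<prefix>_mutations.tsv`, `<prefix>_clinical.tsv`.
#' @return The three paths, invisibly.
#' @export
write_cohort <- function(ch, prefix) {
  stopifnot(inherits(ch, "cohort"))
  pe <- paste0(prefix, "_expression.tsv")
  pm <- paste0(prefix, "_mutations.tsv")
  pc <- paste0(prefix, "_clinical.tsv")
  write_expression(ch$expression, pe)
  dfm <- data.frame(gene = rownames(ch$mutations), unclass(ch$mutations),
                    check.names = FALSE)
  colnames(dfm) <- c("gene", colnames(ch$mutations))
  utils::write.table(dfm, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ch$clinical, pc, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = pe, mutations = pm, clinical = pc))
}

#' Restrict expression, mutation and clinical tables to shared samples
#'
#' Keeps the intersection of the three sample-id sets, in the order the ids
#' appear in the expression matrix, and reports how many samples each table
#' loses. Matching is exact string match after whitespace stripping; no
#' barcode truncation is applied unless `truncate_barcodes` is set, in
#' which case ids are cut to the first `barcode_len` characters
#' (patient-level TCGA matching is 12).
#'
#' @param expr An [expression_matrix()].
#' @param mut A [mutation_matrix()].
#' @param clinical A [clinical_table()].
#' @param truncate_barcodes Opt-in TCGA-style barcode truncation.
#' @param barcode_len Characters kept when truncating.
#' @return A [cohort()] over the shared samples.
#' @export
harmonize <- function(expr, mut, clinical,
                      truncate_barcodes = FALSE, barcode_len = 12L) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(mut, "mutation_matrix"),
            inherits(clinical, "clinical_table"))
  trunc <- function(x) if (truncate_barcodes) substr(x, 1L, barcode_len) else x
  se <- trunc(trimws(colnames(expr)))
  sm <- trunc(trimws(colnames(mut)))
  sc <- trunc(trimws(clinical$sample_id))
  if (anyDuplicated(se) || anyDuplicated(sm) || anyDuplicated(sc)) {
    stop("barcode truncation produced duplicate sample ids")
  }
  shared <- se[se %in% sm & se %in% sc]
  if (length(shared) == 0L) stop("no samples shared across the three tables")
  message(sprintf("harmonize: kept %d samples (dropped %d expression, %d mutation, %d clinical)",
                  length(shared), length(se) - length(shared),
                  length(sm) - length(shared), length(sc) - length(shared)))
  e <- unclass(expr)[, match(shared, se), drop = FALSE]
  colnames(e) <- shared
  m <- unclass(mut)[, match(shared, sm), drop = FALSE]
  colnames(m) <- shared
  cl <- clinical[match(shared, sc), , drop = FALSE]
  cl$sample_id <- shared
  rownames(cl) <- NULL
  cohort(expression_matrix(e, is_log2 = attr(expr, "is_log2")),
         mutation_matrix(m), clinical_table(cl))
}

#' Median-of-ratios size-factor normalization
#'
#' Classic RNA-seq library-size correction: per sample j, the size factor
#' is the median over reference genes of the ratio count\[g, j\] /
#' geometric-mean\[g\], where reference genes are those with strictly
#' positive counts in every sample. Output is counts divided column-wise by
#' the size factors.
#'
#' @param raw_counts Non-negative genes-by-samples matrix (or an
#'   [expression_matrix()]).
#' @return An [expression_matrix()] of normalized values with the size
#'   factors in attribute `size_factors`.
#' @export
size_factor_normalize <- function(raw_counts) {
  m <- unclass(raw_counts)
  if (!is.matrix(m) || !is.numeric(m)) stop("`raw_counts` must be a numeric matrix")
  if (any(m < 0)) stop("counts must be non-negative")
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop("no gene has positive counts in every sample; pre-filter genes first")
  }
  geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  sf <- apply(sweep(m[ref, , drop = FALSE], 1, geo, "/"), 2, stats::median)
  message("size factors: ", paste(sprintf("%s=%.4g", names(sf), sf), collapse = ", "))
  out <- sweep(m, 2, sf, "/")
  res <- expression_matrix(out, is_log2 = FALSE)
  attr(res, "size_factors") <- sf
  res
}
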
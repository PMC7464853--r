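#' Construct a normalized expression matrix
#'
#' Genes-by-samples numeric matrix with unique, non-empty row (gene) and
#' column (sample) names. Values are linear-scale unless `is_log2 = TRUE`;
#' all downstream fold changes assume linear scale.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames and colnames set. All values must be finite and non-negative
#'   (negative values are allowed only when `is_log2 = TRUE`).
#' @param is_log2 Logical flag recording whether values are log2-transformed.
#' @return An `expression_matrix` object (a classed numeric matrix with an
#'   `is_log2` attribute).
#' @export
expression_matrix <- function(values, is_log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  if (!is_log2 && any(values < 0)) {
    stop("negative values in a linear-scale expression matrix")
  }
  structure(values, is_log2 = isTRUE(is_log2),
            class = c("expression_matrix", "matrix", "array"))
}

#' Construct a binary mutation matrix
#'
#' Genes-by-samples 0/1 matrix; 1 marks a sample carrying at least one
#' qualifying somatic mutation in that gene.
#'
#' @param status Numeric or integer matrix of 0/1 values with gene rownames
#'   and sample colnames.
#' @return A `mutation_matrix` object.
#' @seealso [mutation_frequency()]
#' @export
mutation_matrix <- function(status) {
  if (!is.matrix(status)) stop("`status` must be a matrix")
  if ((nrow(status) > 0L && is.null(rownames(status))) || is.null(colnames(status))) {
    stop("mutation matrix needs gene rownames and sample colnames")
  }
  if (is.null(rownames(status))) rownames(status) <- character(0)
  if (anyDuplicated(rownames(status))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(status))) stop("duplicate sample ids")
  if (!all(status %in% c(0L, 1L))) stop("mutation status must be 0/1")
  storage.mode(status) <- "integer"
  structure(status, class = c("mutation_matrix", "matrix", "array"))
}

#' Per-gene mutation frequency
#'
#' @param mut A [mutation_matrix()].
#' @return Named numeric vector: fraction of samples mutated, per gene.
#' @export
mutation_frequency <- function(mut) {
  stopifnot(inherits(mut, "mutation_matrix"))
  rowSums(mut) / ncol(mut)
}

#' Construct a clinical table
#'
#' One row per sample. `time` is survival time in the units of the input
#' (typically months), `event` is 1 for an observed event and 0 for
#' censoring. Optional columns: `subtype` (molecular subtype label),
#' `purity` (tumor purity, fraction of malignant cells in \[0,1\]) and any
#' number of immune-cell abundance columns prefixed `abund_`.
#'
#' @param df Data frame with at least `sample_id`, `time`, `event`.
#' @return A `clinical_table` (classed data frame).
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  ok_time <- is.na(df$time) | df$time >= 0
  if (!all(ok_time)) stop("negative survival times")
  ok_ev <- is.na(df$event) | df$event %in% c(0, 1)
  if (!all(ok_ev)) stop("event indicator must be 0/1")
  if ("purity" %in% names(df)) {
    ok_p <- is.na(df$purity) | (df$purity >= 0 & df$purity <= 1)
    if (!all(ok_p)) stop("purity must lie in [0, 1]")
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Assemble a harmonized multi-omic cohort
#'
#' Bundles an expression matrix, a mutation matrix and a clinical table
#' over an identical, identically ordered sample set. Use [harmonize()] to
#' build one from tables with partially overlapping samples.
#'
#' @param expression An [expression_matrix()].
#' @param mutations A [mutation_matrix()].
#' @param clinical A [clinical_table()].
#' @return A `cohort` object (list with the three components).
#' @export
cohort <- function(expression, mutations, clinical) {
  stopifnot(inherits(expression, "expression_matrix"),
            inherits(mutations, "mutation_matrix"),
            inherits(clinical, "clinical_table"))
  s <- colnames(expression)
  if (!identical(s, colnames(mutations)) ||
      !identical(s, clinical$sample_id)) {
    stop("sample ids differ across components; run harmonize() first")
  }
  structure(list(expression = expression, mutations = mutations,
                 clinical = clinical),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d samples, %d expressed genes, %d mutation genes\n",
              ncol(x$expression), nrow(x$expression), nrow(x$mutations)))
  opt <- intersect(c("subtype", "purity"), names(x$clinical))
  ab <- grep("^abund_", names(x$clinical), value = TRUE)
  cat(sprintf("clinical: time/event%s%s\n",
              if (length(opt)) paste0(" + ", paste(opt, collapse = ", ")) else "",
              if (length(ab)) sprintf(" + %d abundance columns", length(ab)) else ""))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), if (attr(x, "is_log2")) "log2" else "linear"))
  invisible(x)
}

#' @export
print.mutation_matrix <- function(x, ...) {
  f <- mutation_frequency(x)
  cat(sprintf("mutation_matrix: %d genes x %d samples; frequency %.1f%%-%.1f%%\n",
              nrow(x), ncol(x), 100 * min(f), 100 * max(f)))
  invisible(x)
}

# subsetting keeps class + flag (used heavily by harmonize)
#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, is_log2 = attr(x, "is_log2"),
                     class = c("expression_matrix", "matrix", "array"))
  }
  out
}

#' @export
`[.mutation_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    class(out) <- c("mutation_matrix", "matrix", "array")
  }
  out
}
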
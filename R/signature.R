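#' Derive the transcriptomic signature of a mutation
#'
#' Compares every expressed gene between carriers and non-carriers of
#' `mutated_gene` (Mann-Whitney, two-sided), keeps genes with
#' `p < p_max`, orders them by ascending p and truncates to `n_top` —
#' the mutation-associated signature, with each member's direction
#' (`+1` when carriers express it higher).
#'
#' @param ch A harmonized [cohort()].
#' @param mutated_gene Gene whose carriers define the partition; needs at
#'   least 2 carriers and 2 non-carriers.
#' @param n_top Signature size cap (default 100).
#' @param p_max Significance threshold (default 0.05).
#' @return A `mutation_signature`: list with `mutated_gene` and `table`
#'   (gene, p_value, direction, ordered by p).
#' @export
derive_mutation_signature <- function(ch, mutated_gene, n_top = 100L,
                                      p_max = 0.05) {
  stopifnot(inherits(ch, "cohort"))
  if (!mutated_gene %in% rownames(ch$mutations)) {
    stop("gene '", mutated_gene, "' not in mutation matrix")
  }
  carrier <- unclass(ch$mutations)[mutated_gene, ] == 1L
  if (sum(carrier) < 2L || sum(!carrier) < 2L) {
    stop("need at least 2 carriers and 2 non-carriers of ", mutated_gene)
  }
  ev <- unclass(ch$expression)
  n <- ncol(ev)
  if (n <= 16L) {
    p <- apply(ev, 1, function(v) mann_whitney(v[carrier], v[!carrier])$p)
  } else {
    p <- mw_rows(ev, carrier)$p
  }
  dirn <- sign(rowMeans(ev[, carrier, drop = FALSE]) -
               rowMeans(ev[, !carrier, drop = FALSE]))
  tab <- data.frame(gene = rownames(ev), p_value = as.numeric(p),
                    direction = as.numeric(dirn), row.names = NULL)
  tab <- tab[tab$p_value < p_max, , drop = FALSE]
  tab <- tab[order(tab$p_value, tab$gene), , drop = FALSE]
  tab <- utils::head(tab, n_top)
  if (nrow(tab) == 0L) warning("no gene reaches significance: empty signature")
  structure(list(mutated_gene = mutated_gene, table = tab,
                 n_top = n_top, p_max = p_max),
            class = "mutation_signature")
}

#' @export
print.mutation_signature <- function(x, ...) {
  cat(sprintf("mutation_signature for %s: %d genes (p < %g, top %d)\n",
              x$mutated_gene, nrow(x$table), x$p_max, x$n_top))
  invisible(x)
}

#' Score samples by mean signature expression with a median split
#'
#' Per-sample score = mean expression over the listed genes; samples
#' strictly above the cohort-median score form the "high" group, samples
#' at or below it the "low" group (median ties go to "low", so "high"
#' strictly exceeds the median).
#'
#' @param expr An [expression_matrix()] (or a [cohort()], whose expression
#'   is used).
#' @param gene_list Character vector of signature genes, or a
#'   `mutation_signature`. Genes absent from the matrix are dropped with a
#'   warning; all absent is an error.
#' @return Data frame `sample_id`, `score`, `group` (factor low/high, low
#'   first so it is the reference level downstream).
#' @export
score_samples <- function(expr, gene_list) {
  if (inherits(expr, "cohort")) expr <- expr$expression
  stopifnot(inherits(expr, "expression_matrix"))
  if (inherits(gene_list, "mutation_signature")) gene_list <- gene_list$table$gene
  if (inherits(gene_list, "signature_gene_list")) gene_list <- gene_list$genes
  gene_list <- unique(as.character(gene_list))
  present <- gene_list %in% rownames(expr)
  if (!any(present)) stop("none of the signature genes are in the expression matrix")
  if (any(!present)) {
    warning("dropped ", sum(!present), " signature gene(s) absent from matrix: ",
            paste(gene_list[!present], collapse = ", "))
  }
  sc <- colMeans(unclass(expr)[gene_list[present], , drop = FALSE])
  med <- stats::median(sc)
  data.frame(sample_id = colnames(expr), score = as.numeric(sc),
             group = factor(ifelse(sc > med, "high", "low"),
                            levels = c("low", "high")),
             row.names = NULL)
}

#' Seven-gene joint immune signature score
#'
#' [score_samples()] with the default joint gene set derived from the
#' RYR2/AHNAK mutation signatures (CXCL9, GBP5, C1QA, IL2RG, CSF2RB, IDO1,
#' LAG3); the set is overridable.
#'
#' @param expr An [expression_matrix()] or [cohort()].
#' @param genes Gene set; defaults to the seven-gene signature.
#' @return As [score_samples()].
#' @export
joint_gene_score <- function(expr,
                             genes = c("CXCL9", "GBP5", "C1QA", "IL2RG",
                                       "CSF2RB", "IDO1", "LAG3")) {
  score_samples(expr, genes)
}
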
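#' Mutation co-occurrence: 2x2 odds ratio with Fisher's exact test
#'
#' Cross-tabulates the two genes' mutation statuses across samples.
#' The odds ratio is the sample cross-product `(n11*n00)/(n10*n01)`
#' (Inf when a discordant cell is 0 and the numerator is positive); the
#' two-sided Fisher p sums central-hypergeometric probabilities of all
#' tables (fixed margins) no more probable than the observed one.
#'
#' @param mut A [mutation_matrix()].
#' @param geneA,geneB Gene ids, both present in the matrix.
#' @return A `cooccurrence_result`: list with `geneA`, `geneB`, `counts`
#'   (n11 both, n10 A only, n01 B only, n00 neither), `odds_ratio`, `p`.
#' @export
cooccurrence <- function(mut, geneA, geneB) {
  stopifnot(inherits(mut, "mutation_matrix"))
  for (g in c(geneA, geneB)) {
    if (!g %in% rownames(mut)) stop("gene '", g, "' not in mutation matrix")
  }
  a <- unclass(mut)[geneA, ]
  b <- unclass(mut)[geneB, ]
  n11 <- sum(a == 1L & b == 1L); n10 <- sum(a == 1L & b == 0L)
  n01 <- sum(a == 0L & b == 1L); n00 <- sum(a == 0L & b == 0L)
  or <- if (n10 == 0L || n01 == 0L) {
    if (n11 == 0L || n00 == 0L) NaN else Inf
  } else (n11 * n00) / (n10 * n01)
  structure(list(geneA = geneA, geneB = geneB,
                 counts = c(n11 = n11, n10 = n10, n01 = n01, n00 = n00),
                 odds_ratio = or,
                 p = fisher_exact_p(n11, n10, n01, n00)),
            class = "cooccurrence_result")
}

# two-sided Fisher exact p: sum of hypergeometric probabilities <= the
# observed table's probability (with a small relative tolerance against
# floating-point equality, the convention of common implementations)
fisher_exact_p <- function(n11, n10, n01, n00) {
  m <- n11 + n10            # A-mutated
  n <- n01 + n00            # A-wild-type
  k <- n11 + n01            # B-mutated
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(n11, m, n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat(sprintf("co-occurrence %s / %s: OR = %.3g, Fisher p = %.3g (n11=%d n10=%d n01=%d n00=%d)\n",
              x$geneA, x$geneB, x$odds_ratio, x$p,
              x$counts["n11"], x$counts["n10"], x$counts["n01"], x$counts["n00"]))
  invisible(x)
}

#' Purity-corrected partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and the covariate `z` (midranks for ties) and
#' computes the first-order partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` on the
#' ranks, with a t-test on n-3 degrees of freedom. When `z` is constant
#' the plain Spearman correlation is returned instead (noted via a
#' message, and in the `covariate` field).
#'
#' @param x,y,z Equal-length numeric vectors, `n >= 5`.
#' @param covariate Label for the adjustment covariate (default "purity").
#' @return A `partial_correlation`: list `rho`, `p`, `n`, `covariate`.
#' @export
partial_spearman <- function(x, y, z, covariate = "purity") {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 5L) stop("need n >= 5 for a partial correlation")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(z) == 0) {
    message("covariate has zero variance; returning plain Spearman correlation")
    r <- stats::cor(rx, ry)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    return(structure(list(rho = r,
                          p = 2 * stats::pt(-abs(tt), df = n - 2),
                          n = n, covariate = "none"),
                     class = "partial_correlation"))
  }
  rz <- rank(z)
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("a variable is perfectly rank-correlated with the covariate; partial correlation undefined")
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- min(1, max(-1, r))
  tt <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  structure(list(rho = r, p = 2 * stats::pt(-abs(tt), df = n - 3),
                 n = n, covariate = covariate),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("partial Spearman rho = %.3f (vs %s), p = %.3g, n = %d\n",
              x$rho, x$covariate, x$p, x$n))
  invisible(x)
}

#' Immune-infiltration correlation profile of one gene
#'
#' For each requested cell type, the purity-corrected partial Spearman
#' correlation between the gene's expression and the `abund_<cell_type>`
#' clinical column; plus the plain Spearman correlation of expression with
#' tumor purity itself (first row).
#'
#' @param ch A [cohort()] whose clinical table carries `purity` and
#'   `abund_*` columns.
#' @param gene Gene id in the expression matrix.
#' @param cell_types Cell types to profile; default all `abund_*` columns.
#' @return Data frame `gene`, `covariate`, `rho`, `p`, `n`.
#' @export
infiltration_profile <- function(ch, gene, cell_types = NULL) {
  stopifnot(inherits(ch, "cohort"))
  clin <- ch$clinical
  if (!"purity" %in% names(clin)) stop("clinical table has no purity column")
  if (!gene %in% rownames(ch$expression)) stop("gene '", gene, "' not in expression matrix")
  avail <- sub("^abund_", "", grep("^abund_", names(clin), value = TRUE))
  if (is.null(cell_types)) cell_types <- avail
  miss <- setdiff(cell_types, avail)
  if (length(miss)) {
    stop("abundance column(s) missing for: ", paste(miss, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  }
  ex <- as.vector(unclass(ch$expression)[gene, ])
  n <- length(ex)
  rho_p <- stats::cor(rank(ex), rank(clin$purity))
  tt <- rho_p * sqrt((n - 2) / max(1 - rho_p^2, .Machine$double.eps))
  rows <- list(data.frame(gene = gene, covariate = "purity", rho = rho_p,
                          p = 2 * stats::pt(-abs(tt), df = n - 2), n = n))
  for (ct in cell_types) {
    pc <- partial_spearman(ex, clin[[paste0("abund_", ct)]], clin$purity)
    rows[[length(rows) + 1L]] <- data.frame(gene = gene, covariate = ct,
                                            rho = pc$rho, p = pc$p, n = pc$n)
  }
  do.call(rbind, rows)
}

#' Pearson correlation of two genes on the log2 scale
#'
#' Pearson correlation of `log2(x + 1)` vs `log2(y + 1)` with the usual
#' t-based p on n-2 degrees of freedom.
#'
#' @param expr_a,expr_b Linear-scale expression vectors, `n >= 3`.
#' @return List `r`, `p`, `n`.
#' @export
pearson_log2 <- function(expr_a, expr_b) {
  n <- length(expr_a)
  if (length(expr_b) != n) stop("vectors must have equal length")
  if (n < 3L) stop("need n >= 3")
  la <- log2(expr_a + 1); lb <- log2(expr_b + 1)
  if (stats::var(la) == 0 || stats::var(lb) == 0) {
    stop("zero variance after log2 transform; correlation undefined")
  }
  ct <- stats::cor.test(la, lb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' FDR-based selection of highly expressed, outcome-favorable genes
#'
#' Benjamini-Hochberg correction is applied separately to the RFS and OS
#' p-value vectors; a gene is kept when both adjusted p-values fall below
#' `q`, both hazard ratios are below 1 (when `require_favorable`), and its
#' median expression is at or above the `expr_min_quantile` quantile of
#' the reference expression distribution.
#'
#' @param candidates Data frame with columns `gene`, `p_rfs`, `p_os`,
#'   `hr_rfs`, `hr_os`, `median_expr`.
#' @param q FDR threshold (default 0.01).
#' @param expr_min_quantile Expression-level quantile cutoff in \[0, 1\]
#'   (default 0.5); 0 disables the expression filter.
#' @param expr_ref Reference vector of per-gene median expression defining
#'   the quantile (defaults to `candidates$median_expr`; pass all-gene
#'   medians to anchor "highly expressed" cohort-wide).
#' @param require_favorable Require HR < 1 for both endpoints.
#' @return The selected rows of `candidates`, with `q_rfs`, `q_os` added,
#'   ordered by the larger adjusted p.
#' @export
select_genes_fdr <- function(candidates, q = 0.01, expr_min_quantile = 0.5,
                             expr_ref = NULL, require_favorable = TRUE) {
  need <- c("gene", "p_rfs", "p_os", "hr_rfs", "hr_os", "median_expr")
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop("candidate table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(candidates) == 0L) stop("empty candidate table")
  out <- candidates
  out$q_rfs <- stats::p.adjust(out$p_rfs, method = "BH")
  out$q_os <- stats::p.adjust(out$p_os, method = "BH")
  if (is.null(expr_ref)) expr_ref <- candidates$median_expr
  thr <- stats::quantile(expr_ref, expr_min_quantile, names = FALSE)
  keep <- out$q_rfs < q & out$q_os < q & out$median_expr >= thr
  if (require_favorable) keep <- keep & out$hr_rfs < 1 & out$hr_os < 1
  out <- out[keep, , drop = FALSE]
  out[order(pmax(out$q_rfs, out$q_os), out$gene), , drop = FALSE]
}
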
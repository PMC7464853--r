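#' Fold change of marker expression between carriers and wild type
#'
#' Ratio of group means on the linear scale with a pseudocount guarding
#' against zero wild-type expression:
#' `FC = (mean(mut) + pseudocount) / (mean(wt) + pseudocount)`.
#'
#' @param expr_mut Marker expression in mutation carriers.
#' @param expr_wt Marker expression in wild-type samples.
#' @param pseudocount Added to both group means; default 1.
#' @return The fold change (NA with a warning when either group is empty).
#' @export
marker_fold_change <- function(expr_mut, expr_wt, pseudocount = 1) {
  if (length(expr_mut) == 0L || length(expr_wt) == 0L) {
    warning("empty group: fold change undefined")
    return(NA_real_)
  }
  (mean(expr_mut) + pseudocount) / (mean(expr_wt) + pseudocount)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is the rank-sum statistic for `x` (midranks for ties). With
#' `mode = "auto"` the p-value is exact — from the null U distribution,
#' equivalent to enumerating all group labelings — when the pooled size is
#' at most 16 and there are no ties; otherwise it uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param mode `"auto"`, `"exact"` (ties forbidden) or `"approx"`.
#' @return List with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(mode,
                      exact = TRUE,
                      approx = FALSE,
                      auto = (n1 + n2) <= 16L && !ties)
  if (use_exact) {
    if (ties) stop("exact mode requires tie-free data")
    # two-sided tail of the symmetric exact null U distribution
    lower <- stats::pwilcox(U, n1, n2)
    upper <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
  } else {
    p <- mw_normal_p(U, n1, n2, tie_term = sum_tie_term(r))
  }
  list(U = U, p = p)
}

# sum over tie groups of (t^3 - t), from a midrank vector
sum_tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

# normal approximation with tie + continuity correction (two-sided)
mw_normal_p <- function(U, n1, n2, tie_term = 0) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(rep(1, length(U)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  pmin(1, 2 * stats::pnorm(-abs(z)))
}

# Mann-Whitney of one fixed value vector against many binary partitions:
# rank once, then U_g = sum of carrier ranks - n1(n1+1)/2 for each row of
# the 0/1 partition matrix. Normal-approximation p (the genome-wide path).
mw_partitions <- function(values, partitions) {
  r <- rank(values)
  n <- length(values)
  n1 <- rowSums(partitions)
  U <- as.vector(partitions %*% r) - n1 * (n1 + 1) / 2
  tie_term <- sum_tie_term(r)
  p <- vapply(seq_along(U), function(i) {
    mw_normal_p(U[i], n1[i], n - n1[i], tie_term)
  }, numeric(1))
  list(U = U, p = p, n1 = n1)
}

# Mann-Whitney of many value rows against one fixed binary partition.
mw_rows <- function(values, carrier) {
  n <- ncol(values)
  n1 <- sum(carrier)
  rk <- t(apply(values, 1, rank))
  U <- rowSums(rk[, carrier, drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_terms <- apply(rk, 1, sum_tie_term)
  p <- vapply(seq_along(U), function(i) {
    mw_normal_p(U[i], n1, n - n1, tie_terms[i])
  }, numeric(1))
  list(U = U, p = p)
}

#' Screen mutations for association with marker expression
#'
#' The discovery stage: for every gene mutated in at least `freq_min` of
#' the cohort, compare the marker gene's expression between that gene's
#' mutation carriers and wild-type samples (Mann-Whitney, two-sided) and
#' compute the carrier/wild-type fold change. Genes with `p < p_max` and
#' `FC > fc_min` are retained, ranked by mutation frequency (descending;
#' ties broken by ascending p, then gene id) and truncated to `top_k` —
#' the frequency-ranked marker signature.
#'
#' @param ch A harmonized [cohort()].
#' @param marker_gene Marker whose expression is compared (e.g. `"PD1"`).
#' @param p_max Mann-Whitney p threshold (default 0.05).
#' @param fc_min Fold-change threshold, strict (default 1.5).
#' @param freq_min Minimum mutation frequency (default 0.02).
#' @param top_k Signature size cap (default 50).
#' @param pseudocount Passed to [marker_fold_change()].
#' @return List of class `screen_result`: `signature` (a
#'   `signature_gene_list`: ordered gene vector + thresholds), `table`
#'   (per-gene data frame: gene, n_mut, frequency, fold_change, p_value,
#'   and rank for retained genes), `marker`.
#' @export
screen_marker <- function(ch, marker_gene, p_max = 0.05, fc_min = 1.5,
                          freq_min = 0.02, top_k = 50L, pseudocount = 1) {
  stopifnot(inherits(ch, "cohort"))
  if (!marker_gene %in% rownames(ch$expression)) {
    stop("marker gene '", marker_gene, "' not in expression matrix")
  }
  mval <- as.vector(unclass(ch$expression)[marker_gene, ])
  n <- length(mval)
  freq <- mutation_frequency(ch$mutations)
  cand <- names(freq)[freq >= freq_min]
  nmut <- rowSums(ch$mutations)[cand]
  # Mann-Whitney is degenerate below 2 per group
  testable <- nmut >= 2L & (n - nmut) >= 2L
  if (any(!testable)) {
    message(sprintf("screen: skipped %d gene(s) with < 2 carriers or < 2 wild-type",
                    sum(!testable)))
  }
  cand <- cand[testable]
  tab <- data.frame(gene = cand, n_mut = as.integer(nmut[testable]),
                    frequency = as.numeric(freq[cand]),
                    fold_change = NA_real_, p_value = NA_real_,
                    row.names = NULL)
  if (nrow(tab)) {
    part <- unclass(ch$mutations)[cand, , drop = FALSE]
    if (n <= 16L) {
      # small cohorts: per-gene exact-capable test
      for (i in seq_len(nrow(tab))) {
        carr <- part[i, ] == 1L
        tab$p_value[i] <- mann_whitney(mval[carr], mval[!carr])$p
      }
    } else {
      tab$p_value <- mw_partitions(mval, part)$p
    }
    tab$fold_change <- vapply(seq_len(nrow(tab)), function(i) {
      carr <- part[i, ] == 1L
      marker_fold_change(mval[carr], mval[!carr], pseudocount)
    }, numeric(1))
  }
  keep <- tab$p_value < p_max & tab$fold_change > fc_min
  kept <- tab[keep, , drop = FALSE]
  kept <- kept[order(-kept$frequency, kept$p_value, kept$gene), , drop = FALSE]
  kept <- utils::head(kept, top_k)
  tab$rank <- NA_integer_
  tab$rank[match(kept$gene, tab$gene)] <- seq_len(nrow(kept))
  sig <- structure(list(marker = marker_gene, genes = kept$gene,
                        frequency = kept$frequency,
                        thresholds = list(p_max = p_max, fc_min = fc_min,
                                          freq_min = freq_min, top_k = top_k)),
                   class = "signature_gene_list")
  structure(list(signature = sig, table = tab, marker = marker_gene),
            class = "screen_result")
}

#' @export
print.signature_gene_list <- function(x, ...) {
  cat(sprintf("signature_gene_list (%s): %d genes\n",
              paste(x$marker, collapse = "+"), length(x$genes)))
  if (length(x$genes)) cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
                           if (length(x$genes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Intersect two marker signatures
#'
#' Genes present in both lists, ordered by the larger of their two
#' frequencies (descending, ties by gene id) — the joint marker signature.
#'
#' @param listA,listB `signature_gene_list` objects from [screen_marker()].
#' @return A `signature_gene_list` over the intersection.
#' @export
intersect_signatures <- function(listA, listB) {
  stopifnot(inherits(listA, "signature_gene_list"),
            inherits(listB, "signature_gene_list"))
  common <- intersect(listA$genes, listB$genes)
  if (length(common) == 0L) warning("signature intersection is empty")
  fmax <- pmax(listA$frequency[match(common, listA$genes)],
               listB$frequency[match(common, listB$genes)])
  ord <- order(-fmax, common)
  structure(list(marker = c(listA$marker, listB$marker),
                 genes = common[ord], frequency = fmax[ord],
                 thresholds = listA$thresholds),
            class = "signature_gene_list")
}

#' Re-rank a joint gene list by pooled mutation frequency
#'
#' Pools mutation counts over one or more cohorts' mutation matrices
#' (pooled frequency = total mutated samples / total samples) and keeps
#' genes strictly above `freq_min`, ranked descending. This mirrors
#' widening discovery-cohort gene lists with additional cohorts to favor
#' alterations common in the general population.
#'
#' @param genes Character vector (or `signature_gene_list`) of candidates.
#' @param mut_list A [mutation_matrix()] or list of them.
#' @param freq_min Strict pooled-frequency threshold (default 0.03).
#' @return Data frame `gene`, `n_mut`, `n_total`, `pooled_frequency`,
#'   ranked descending (ties by gene id), retained genes only.
#' @export
combined_frequency_rank <- function(genes, mut_list, freq_min = 0.03) {
  if (inherits(genes, "signature_gene_list")) genes <- genes$genes
  if (inherits(mut_list, "mutation_matrix")) mut_list <- list(mut_list)
  stopifnot(length(mut_list) >= 1L, length(genes) >= 1L)
  n_mut <- stats::setNames(numeric(length(genes)), genes)
  n_total <- 0L
  for (m in mut_list) {
    stopifnot(inherits(m, "mutation_matrix"))
    n_total <- n_total + ncol(m)
    present <- genes %in% rownames(m)
    if (any(!present)) {
      message("combined_frequency_rank: gene(s) absent from a cohort count 0 there: ",
              paste(genes[!present], collapse = ", "))
    }
    n_mut[genes[present]] <- n_mut[genes[present]] +
      rowSums(m[genes[present], , drop = FALSE])
  }
  out <- data.frame(gene = genes, n_mut = as.integer(n_mut),
                    n_total = n_total,
                    pooled_frequency = as.numeric(n_mut) / n_total,
                    row.names = NULL)
  out <- out[out$pooled_frequency > freq_min, , drop = FALSE]
  out[order(-out$pooled_frequency, out$gene), , drop = FALSE]
}
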
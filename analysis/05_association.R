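#!/usr/bin/env Rscript
# Stage 5: immune-infiltration and expression correlates, FDR selection.
#
# For each gene of the seven-gene signature: purity-corrected partial
# Spearman correlations with the immune-cell abundance columns (plus the
# plain Spearman against purity itself), the log2-scale Pearson
# correlation with PDL1 expression, and a per-gene median-split Cox fit
# feeding the Benjamini-Hochberg (FDR < 1%) selection of highly expressed,
# outcome-favorable genes. The simulated cohort carries a single
# time/event endpoint, so the same fit serves both endpoint slots of the
# selection table.

suppressPackageStartupMessages(library(mutscreen))

outdir <- "results/association"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression("results/cohort/cohort_expression.tsv")
mut <- read_mutation_matrix("results/cohort/cohort_mutations.tsv")
clin <- read_clinical("results/cohort/cohort_clinical.tsv")
ch <- harmonize(expr, mut, clin)

genes7 <- c("CXCL9", "GBP5", "C1QA", "IL2RG", "CSF2RB", "IDO1", "LAG3")

profiles <- do.call(rbind, lapply(genes7, function(g) {
  infiltration_profile(ch, g)
}))
utils::write.csv(profiles, file.path(outdir, "infiltration_profiles.csv"),
                 row.names = FALSE)
strong <- profiles[profiles$covariate != "purity" & profiles$rho > 0.3, ]
cat("infiltration links with partial rho > 0.3:\n")
print(strong, row.names = FALSE)

pdl1 <- as.vector(unclass(ch$expression)["PDL1", ])
cors <- do.call(rbind, lapply(genes7, function(g) {
  r <- pearson_log2(as.vector(unclass(ch$expression)[g, ]), pdl1)
  data.frame(gene = g, r = r$r, p = r$p)
}))
utils::write.csv(cors, file.path(outdir, "pdl1_correlation.csv"),
                 row.names = FALSE)
cat("log2 Pearson correlation with PDL1:\n")
print(cors, row.names = FALSE)

cand <- do.call(rbind, lapply(genes7, function(g) {
  sc <- score_samples(ch$expression, g)
  fit <- survival_by_signature(ch, sc)
  data.frame(gene = g, p_rfs = fit$p_wald, p_os = fit$p_wald,
             hr_rfs = fit$hr, hr_os = fit$hr,
             median_expr = stats::median(unclass(ch$expression)[g, ]))
}))
all_medians <- apply(unclass(ch$expression), 1, stats::median)
selected <- select_genes_fdr(cand, q = 0.01, expr_min_quantile = 0.5,
                             expr_ref = all_medians)
utils::write.csv(selected, file.path(outdir, "fdr_selected_genes.csv"),
                 row.names = FALSE)
cat(sprintf("FDR < 1%% favorable, highly expressed genes: %s\n",
            paste(selected$gene, collapse = ", ")))
cat("wrote", outdir, "\n")
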
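#!/usr/bin/env Rscript
# Stage 3: transcriptomic signatures of the selected mutations.
#
# For each gene surviving the pooled-frequency filter: test co-occurrence
# of the top pair, derive the mutation-associated expression signature
# (genome-wide carrier vs non-carrier Mann-Whitney, top 100 by p), score
# every sample by mean signature expression, median-split, and compare
# survival of the high vs low group by Cox regression.

suppressPackageStartupMessages(library(mutscreen))

outdir <- "results/signatures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression("results/cohort/cohort_expression.tsv")
mut <- read_mutation_matrix("results/cohort/cohort_mutations.tsv")
clin <- read_clinical("results/cohort/cohort_clinical.tsv")
ch <- harmonize(expr, mut, clin)
pooled <- utils::read.csv("results/screen/pooled_frequency.csv")

if (nrow(pooled) >= 2) {
  cr <- cooccurrence(ch$mutations, pooled$gene[1], pooled$gene[2])
  print(cr)
  utils::write.csv(
    data.frame(geneA = cr$geneA, geneB = cr$geneB, t(cr$counts),
               odds_ratio = cr$odds_ratio, p = cr$p),
    file.path(outdir, "cooccurrence.csv"), row.names = FALSE)
}

fits <- list()
for (g in pooled$gene) {
  sig <- derive_mutation_signature(ch, g, n_top = 100)
  utils::write.csv(sig$table, file.path(outdir, paste0("signature_", g, ".csv")),
                   row.names = FALSE)
  sc <- score_samples(ch$expression, sig)
  fit <- survival_by_signature(ch, sc)
  fits[[g]] <- fit
  cat(sprintf("%s: %d signature genes; high-vs-low HR %.2f (95%% CI %.2f-%.2f), p = %.2g\n",
              g, nrow(sig$table), fit$hr, fit$ci[1], fit$ci[2], fit$p_wald))
}

utils::write.csv(
  do.call(rbind, lapply(names(fits), function(g) {
    f <- fits[[g]]
    data.frame(mutated_gene = g, hr = f$hr, ci_lower = f$ci[1],
               ci_upper = f$ci[2], p_wald = f$p_wald, p_logrank = f$p_logrank)
  })),
  file.path(outdir, "signature_survival.csv"), row.names = FALSE)
cat("wrote", outdir, "\n")
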
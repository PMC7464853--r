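#!/usr/bin/env Rscript
# Stage 2: screen mutations for association with marker-high expression.
#
# For each marker (PD1, PDL1): Mann-Whitney comparison of the marker's
# expression between each gene's mutation carriers and wild-type samples,
# fold-change and frequency filters (p < 0.05, FC > 1.5, frequency >= 2%),
# frequency-descending ranking, top 50. The two marker signatures are then
# intersected and the joint list re-ranked by pooled mutation frequency
# (> 3% retained).

suppressPackageStartupMessages(library(mutscreen))

outdir <- "results/screen"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression("results/cohort/cohort_expression.tsv")
mut <- read_mutation_matrix("results/cohort/cohort_mutations.tsv")
clin <- read_clinical("results/cohort/cohort_clinical.tsv")
ch <- harmonize(expr, mut, clin)

screens <- lapply(c(PD1 = "PD1", PDL1 = "PDL1"), function(mk) {
  res <- screen_marker(ch, mk)
  utils::write.csv(res$table, file.path(outdir, paste0("screen_", mk, ".csv")),
                   row.names = FALSE)
  cat(sprintf("%s screen: %d candidate genes tested, %d retained; top 5: %s\n",
              mk, nrow(res$table), length(res$signature$genes),
              paste(utils::head(res$signature$genes, 5), collapse = ", ")))
  res
})

joint <- intersect_signatures(screens$PD1$signature, screens$PDL1$signature)
writeLines(joint$genes, file.path(outdir, "joint_signature.txt"))
cat(sprintf("joint signature (both markers): %d genes\n", length(joint$genes)))

pooled <- combined_frequency_rank(joint, ch$mutations, freq_min = 0.03)
utils::write.csv(pooled, file.path(outdir, "pooled_frequency.csv"),
                 row.names = FALSE)
cat("genes altered in more than 3% of patients, by pooled frequency:\n")
print(pooled, row.names = FALSE)
cat("wrote", outdir, "\n")
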
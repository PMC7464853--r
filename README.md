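# mutscreen

Mutation-association screening, transcriptomic signatures and survival
analysis for immune-marker-high tumors.

## The problem

Checkpoint-inhibitor therapy works best in tumors that are already in an
immune pre-activated state, commonly flagged by high transcript levels of
the PD1 receptor and its ligand PD-L1. A natural discovery question in a
multi-omic cancer cohort (expression + somatic mutations + clinical
follow-up) is:

1. **Which genes' mutations co-occur with elevated marker expression?**
   For every gene, split the cohort into mutation carriers and wild type,
   compare the marker's expression by a two-sided Mann–Whitney test and a
   carrier/wild-type fold change FC = (mean_mut + 1)/(mean_wt + 1), keep
   genes with p < 0.05, FC > 1.5 and mutation frequency ≥ 2%, rank by
   frequency and keep the top 50. Intersecting the PD1 and PD-L1 lists
   gives a joint signature; re-ranking by pooled frequency across cohorts
   (> 3% retained) favors alterations common in the general population.
2. **What do those mutations do to the transcriptome?** For a selected
   mutation, the genome-wide carrier vs non-carrier Mann–Whitney screen
   (top 100 genes by p) defines its mutation-associated signature.
3. **Does the signature predict outcome?** Samples are scored by the mean
   expression of the signature genes, median-split into high/low, and
   compared with a univariate Cox proportional-hazards fit (Efron ties;
   low = reference, so HR < 1 means high expression is favorable), plus
   Kaplan–Meier curves and a log-rank test.
4. **Is it immune-related?** Mutation pairs are tested for co-occurrence
   (2×2 odds ratio, two-sided Fisher exact test); gene expression is
   correlated with immune-cell abundances by purity-corrected partial
   Spearman correlation (tumor purity is the confounder: low purity means
   more non-malignant cells), and with other genes by Pearson correlation
   on log2 values. A Benjamini–Hochberg filter (FDR < 1%) selects highly
   expressed genes favorable for both endpoints.

Every stage is implemented as a package function, and a seeded synthetic
cohort generator plants each assumed effect (marker fold changes,
co-occurrence odds ratios, proportional-hazards survival signal,
purity-confounded infiltration links) so the whole pipeline is verifiable
at desk scale without external cohort downloads.

## Worked example

```r
library(mutscreen)

genes7 <- c("CXCL9", "GBP5", "C1QA", "IL2RG", "CSF2RB", "IDO1", "LAG3")
cfg <- sim_config(
  n_samples = 600, n_genes = 300,
  planted_mut_genes = data.frame(gene = c("RYR2", "AHNAK"),
                                 frequency = c(0.15, 0.12),
                                 fold_change = c(2, 2)),
  cooccurrence_pairs = data.frame(geneA = "RYR2", geneB = "AHNAK",
                                  odds_ratio = 4),
  signature_genes = data.frame(gene = genes7, beta = rep(-0.35, 7)),
  baseline_hazard = 0.02, censoring_rate = 0.3, seed = 20260930)
ch <- generate_cohort(cfg)$cohort

screen_marker(ch, "PD1")$signature
#> signature_gene_list (PD1): 6 genes
#>   RYR2, AHNAK, gene0048, gene0221, gene0243, gene0010

cooccurrence(ch$mutations, "RYR2", "AHNAK")
#> co-occurrence RYR2 / AHNAK: OR = 5.66, Fisher p = 7.7e-10
#>   (n11=32 n10=61 n01=43 n00=464)

survival_by_signature(ch, joint_gene_score(ch$expression))
#> Cox fit (high vs low [ref]): HR 0.299 (95% CI 0.242-0.37),
#>   Wald p = 9.77e-29, log-rank p = 1.14e-31
#> n = 300/300, events = 253/149 (low/high)
```

The planted mutations top the marker screen, their co-occurrence odds
ratio (planted at 4) is recovered with a significant Fisher p, and the
high-scoring half of the cohort for the planted favorable signature shows
an HR well below 1.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the study end
to end on a simulated cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort TSVs + planted truth
Rscript analysis/02_screen_markers.R         # PD1/PD-L1 screens, joint list
Rscript analysis/03_mutation_signatures.R    # co-occurrence + signatures
Rscript analysis/04_joint_signature_survival.R
Rscript analysis/05_association.R            # infiltration, correlation, FDR
```

`run_pipeline(pipeline_config(...))` performs the same sequence in one
call, from TSV inputs or a `sim_config`, and writes per-stage CSVs, a
JSON summary and a reproducible log.

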
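---
title: "Methods: mutation-association screening, signatures and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-association screening, signatures and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscreen)
```

## Overview

`mutscreen` implements a discovery chain for multi-omic tumor cohorts:
find genes whose somatic mutations associate with elevated expression of
immune-checkpoint markers (PD1, PD-L1), derive the transcriptomic
signature of the selected mutations, score samples by mean signature
expression, and evaluate the score against survival, mutation
co-occurrence and immune-infiltration correlates. This vignette explains
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-cohort generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Data model

A `cohort` bundles three tables over one identically ordered sample set:

* `expression_matrix` — genes × samples, linear scale unless flagged
  log2. All fold changes are computed on the linear scale.
* `mutation_matrix` — 0/1 genes × samples; 1 means the sample carries at
  least one qualifying variant in the gene. When built from a MAF
  (`read_maf()`), Silent variants are excluded by default; this is a
  configurable choice (`excluded_classes`), since "mutated" is often
  defined without a class filter and the right filter depends on the
  upstream caller.
* `clinical_table` — `sample_id`, `time` (input units, nominally months),
  `event` (1 = observed), optional `subtype`, `purity` ∈ [0,1] and any
  number of `abund_*` immune-abundance columns. Abundances are inputs:
  no deconvolution is performed here.

`harmonize()` intersects sample ids (exact string match after whitespace
stripping; TCGA-style barcode truncation is opt-in, never automatic,
because silent truncation can merge distinct aliquots) and reports the
dropped-sample count per table. Duplicate gene rows in an expression file
are collapsed by arithmetic mean with a warning — a deliberate neutral
default where no aggregation rule is canonical.

`size_factor_normalize()` implements median-of-ratios library-size
correction: with reference genes `G` (strictly positive in every
sample), the factor of sample `j` is the median over `g ∈ G` of
`c_gj / geomean(c_g.)`. The median is taken on the ratios themselves (not
in log space), matching the estimator's plain definition; the two agree
whenever the reference-gene count is odd. Size factors are defined only
up to a shared constant, so the scale-equivariance property (scaling one
column by `k` scales its factor by `k`) holds for factor *ratios* between
columns, and the tests check it that way.

## The marker screen

For marker `m` and every gene `g` mutated in at least `freq_min` of the
cohort, the cohort splits into carriers and wild type and the marker's
expression is compared by a two-sided Mann–Whitney test;
`FC_g = (mean_mut + 1) / (mean_wt + 1)`. Genes with `p < p_max` and
`FC > fc_min` are ranked by mutation frequency (descending) and truncated
to `top_k`.

Defaults: `p_max = 0.05`, `fc_min = 1.5`, `freq_min = 0.02`,
`top_k = 50`. No multiple-testing correction is applied inside the
screen — the joint p + FC + frequency filter is the screening device, and
FDR control is reserved for the later gene-selection stage
(`select_genes_fdr()`).

Choices worth stating:

* **FC definition.** Ratio of arithmetic group means with pseudocount 1 on
  the linear scale. The pseudocount guards against all-zero wild-type
  groups; means (not medians) keep the statistic sensitive to the
  multiplicative shifts the generator plants. FC filters only in the
  upward direction (`FC > fc_min`): the screen looks for mutations whose
  carriers *over*-express the marker.
* **Ranking ties.** Frequency ties break by ascending p, then gene id, so
  output order is fully deterministic.
* **Degenerate genes.** Fewer than 2 carriers or 2 wild-type samples make
  the Mann–Whitney degenerate; such genes are skipped and counted in a
  message rather than tested.
* **Frequency scope.** Frequencies are computed on the whole harmonized
  cohort, not within a marker-high subset.

`intersect_signatures()` orders the common genes of two marker lists by
the larger of their two frequencies; `combined_frequency_rank()` pools
mutation counts across cohorts (a gene absent from a cohort contributes
zero there) and keeps genes *strictly* above `freq_min = 0.03` — the
boundary is strict, so a pooled frequency of exactly 3% is excluded.

### Mann–Whitney implementation

`mann_whitney()` computes the rank-sum U with midranks. With pooled size
≤ 16 and no ties it uses the exact null distribution of U (equivalent to
enumerating all group labelings; verified against a full `combn()`
enumeration oracle to 1e-10); otherwise the normal approximation with tie
correction and a 0.5 continuity correction. Two internal vectorized paths
serve the genome-wide loops — one ranks the marker once and sweeps
partitions (`screen_marker`), one fixes the partition and sweeps
expression rows (`derive_mutation_signature`) — and both are tested for
exact agreement with the scalar implementation. Cohorts of ≤ 16 samples
fall back to the scalar exact-capable path so the small-sample contract
holds everywhere; at realistic cohort sizes the normal approximation is
the operative branch.

## Mutation signatures and scoring

`derive_mutation_signature()` compares every expressed gene between
carriers and non-carriers of one mutation, keeps `p < 0.05`, orders by
ascending p and truncates to `n_top = 100` (the per-call size is a
parameter: smaller signatures of each mutation can be combined by the
caller when a joint list is wanted). Each member records its direction
(+1 when carriers express it higher).

`score_samples()` scores a sample as the **unsigned mean expression** of
the signature genes and median-splits: samples strictly above the cohort
median are "high", ties at the median go to "low". Direction is exported
but not used in the score; whether down-regulated members should be
subtracted is genuinely open, so the simple mean is the default and the
direction column enables sensitivity analysis. Scoring is invariant to
gene-list order, equivariant under constant shifts, and genes missing
from the matrix are dropped with a warning (all-missing errors).
`joint_gene_score()` is the same scorer with a default seven-gene immune
set (CXCL9, GBP5, C1QA, IL2RG, CSF2RB, IDO1, LAG3).

## Survival comparison

`cox_univariate()` fits a univariate Cox proportional-hazards model on
the binary group via the partial likelihood with **Efron tie handling**
(the better default under tied event times; with no ties it coincides
with Breslow, which is what the brute-force test oracle maximizes). It
reports HR = exp(β̂), the Wald 95% CI and p — the conventional reporting
triplet — plus the log-rank p and per-group Kaplan–Meier curves. The
*low* group is always the reference, so HR < 1 reads "high signature
expression is favorable". Refusals are explicit: a single group is a
degenerate dichotomization, and a group with zero events makes the
partial likelihood monotone (β̂ → ±∞), which is an error with guidance
rather than a huge finite estimate. Samples missing time or event are
dropped with a logged count; `survival_by_signature()` additionally
requires the score table to cover ≥ 90% of the (optionally
subtype-filtered) clinical samples.

## Association statistics

* **Co-occurrence** (`cooccurrence()`): the 2×2 cross-tabulation of two
  genes' statuses; OR is the sample cross-product `n11·n00/(n10·n01)`,
  reported as `Inf` when a discordant cell is 0 (and `NaN` when a
  concordant cell is also 0, leaving the OR undefined). The two-sided
  Fisher p sums central-hypergeometric probabilities of all tables with
  the observed margins that are no more probable than the observed one,
  with a 1e-7 relative tolerance against floating-point equality — the
  convention of common implementations. Note the sample OR is not the
  conditional-MLE OR some tools print; the p-values agree.
* **Partial Spearman** (`partial_spearman()`): ranks (midranks for ties)
  of x, y and the purity covariate z; first-order partial correlation on
  the ranks; t test on n−3 df. A zero-variance covariate falls back to
  plain Spearman with a message. `infiltration_profile()` applies this
  per cell type and also reports the plain Spearman of expression vs
  purity itself.
* **Expression correlation** (`pearson_log2()`): Pearson on
  `log2(x + 1)`, t-based p on n−2 df.
* **FDR selection** (`select_genes_fdr()`): Benjamini–Hochberg applied
  *separately* to the RFS and OS p-vectors (endpoints are reported
  separately, so their error rates are controlled separately); keep genes
  with both adjusted p < q = 0.01, both HR < 1 (favorable) and median
  expression at or above the `expr_min_quantile = 0.5` quantile of a
  reference distribution. "Highly expressed" has no canonical
  definition, so it is operationalized as this quantile rule with the
  reference vector (`expr_ref`) an explicit argument — pass all-gene
  medians to anchor it cohort-wide.

## The synthetic cohort generator

`generate_cohort()` emits a cohort plus the realized truth, from a single
seed. Sub-seeds are derived deterministically per component (expression,
mutations, survival, purity, infiltration), so adding one planted
component never perturbs another's draws.

* **Expression**: log-normal, `meanlog 5`, `sdlog 1` — a heavy-tailed
  positive background typical of linearized RNA-seq abundances.
* **Mutations**: every gene draws Bernoulli status at
  `background_mut_freq = 0.05` (a typical passenger-gene frequency;
  without it, null screens would have nothing to test); planted genes
  override at their configured frequencies, and co-occurrent pairs draw
  jointly from the 2×2 distribution whose marginals and odds ratio are
  requested — `p11` solves the Plackett quadratic, which controls the
  target OR exactly rather than approximately.
* **Marker effect**: carriers of each planted gene have every configured
  marker gene's expression *multiplied* by that gene's fold change,
  matching the ratio-based FC the screen tests.
* **Survival**: exponential baseline (rate `baseline_hazard = 0.01`/month
  by default) with hazard `λ·exp(Σ β_k z_k)` over standardized
  signature-gene expression — the simplest model consistent with the
  proportional-hazards analysis downstream. Censoring is an independent
  exponential whose rate is solved (uniroot on
  `mean(c/(c + h_i)) = censoring_rate`) so the *expected* censored
  fraction matches the request.
* **Purity and infiltration**: purity ~ Beta(5, 2) (right-shifted, as
  tumor purities are); an abundance column is
  `(1 − purity)·exp(latent)`, the latent being a unit normal mixed with
  the linked gene's standardized log-expression. The mixing weight is
  set by the inverse grade-correlation map `ρ_P = 2 sin(πρ/6)` so the
  *Spearman*-scale correlation lands on the requested ρ without post-hoc
  tuning; the `(1 − purity)` factor makes purity a genuine confounder
  that the partial correlation must remove.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real cohorts: empirical gene–gene expression
covariance (genes are independent given the planted effects), batch
effects, subtype composition (every simulated sample is labelled
"basal"), the mutation→transcriptome coupling beyond the configured
marker shifts (so a planted mutation's derived signature contains the
shifted markers, not a broad downstream program), any built-in link
between the seven-gene signature and marker expression, and only one
time/event endpoint is emitted. Results on real data additionally depend
on annotation, normalization and cohort-assembly choices upstream of this
package.

## Verification design and problem sizes

The test-suite and `scripts/acceptance.R` verify the pipeline at sizes a
desk machine handles in minutes, chosen as the smallest scales at which
each property is statistically identifiable: exact-statistic oracle
sweeps (all 2×2 tables with margins ≤ 12; 200 random Mann–Whitney
instances with groups ≤ 8), hand-worked 10-subject Kaplan–Meier and
6-subject Cox fixtures, parameter recovery (Cox HR 2.0 at n = 2000 over
20 seeds; a planted f = 0.05, δ = 2 gene among 2000 background genes at
n = 1000 over 50 seeds; a planted ρ = 0.6 infiltration link at
n = 1000), null calibration (screen type-I error at 1000 genes × 20
seeds; Cox CI coverage over 200 null fits; log-rank p uniformity over
200 seeds), and a 10-seed end-to-end run at n = 600 with 300 background
genes.

One calibration property deserves honesty: with ~50 carriers of
log-normal(sdlog 1) expression, the carrier-mean's coefficient of
variation is ≈ 0.19, so a planted twofold marker shift yields a realized
FC above the 1.5 cutoff in only ≈ 91% of draws. Screen retention of such
a gene therefore plateaus near 0.9, not above 0.95: the limit is the
sampling noise of a heavy-tailed mean, not the test statistic, and it
would sharpen with lighter-tailed expression noise or higher carrier
counts.

## Known limitations

* Survival modeling is deliberately univariate: no multivariate Cox, no
  proportional-hazards diagnostics, no data-driven cutoff optimization —
  the median split is the design.
* The Fisher p convention (sum of ≤-probable tables) and the sample OR
  are one of several defensible pairs; tools using the conditional MLE
  will print different ORs for the same table.
* The normal-approximation Mann–Whitney p is slightly conservative at
  very small carrier counts; genes near the 2-carrier boundary are
  skipped entirely.
* `read_maf()` performs MAF-to-matrix conversion only; variant calling,
  annotation and filtering upstream of the MAF are out of scope, as are
  cohort download clients and immune-cell deconvolution.
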
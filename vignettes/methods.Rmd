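---
title: "Ranking cell-type sensitivity to a perturbation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking cell-type sensitivity to a perturbation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scshift)
```

## The problem

After an in-vivo perturbation — an injury, a drug, a genetic intervention —
different cell types respond to very different degrees. Given droplet
single-cell RNA-seq of perturbed and control animals with cell-type labels
already assigned, `scshift` asks: *which cell types shifted their
transcriptomes the most?* A single statistic is fragile here, because cell
types differ in abundance, sequencing depth and baseline heterogeneity, so
the package computes three complementary resampling metrics per cell type
and aggregates their ranks with equal weight.

All metrics operate on log-normalized expression: per cell, UMI counts are
scaled to a fixed total (10,000 by default) and transformed with the natural
log of 1 + x. Cells enter the analysis only if they show at least 200
detected genes and a mitochondrial UMI fraction strictly below 15%
(`qc_params()`; both thresholds configurable). The natural log is a
convention choice — nothing downstream depends on the base — and the strict
inequality on the mitochondrial bound means a cell at exactly the bound is
removed. Mitochondrial genes are recognised by the mouse-style `mt-` prefix
or an explicit list.

## The three sensitivity metrics

**Euclidean shift** (`euclidean_shift()`). Within one cell type, each of
the top `top_n_genes` most highly expressed genes (default 1000, ranked by
pooled mean; ties broken by gene id) is converted to a z-score across the
pooled cells of both conditions, using the sample (n−1) standard deviation;
zero-variance genes become all-zero rows rather than NaNs. Without the
z-scoring, a handful of very highly expressed genes dominates the distance.
The observed statistic is the Euclidean distance between the two
condition-representative cells — the per-condition mean z-score vectors. The
null re-computes that distance after permuting the condition labels (group
sizes preserved; z-scores and gene selection fixed, which keeps the null
statistic exchangeable with the observed one). The empirical p-value uses
the add-one estimator (1 + #{null ≥ observed}) / (1 + permutations), so it
is never zero, and is Bonferroni-corrected across the cell types tested in
the same tissue × timepoint stratum. The effect size reported for ranking
is `log2(observed / mean(null))`: normalising against the null mean removes
the dependence of raw distance on cell numbers. Both readings — raw
distance and log fold change versus the null — are returned.

**Classifier accuracy** (`svm_shift()`). If the two conditions are
separable in expression space, a classifier should predict condition labels
of held-out cells above chance. Per bootstrap (default 1000), cells are
split 70/30 with stratification by condition, a linear-kernel soft-margin
SVM with cost 1 is fit on the training cells over the same top expressed
genes, and held-out accuracy is recorded; the median over bootstraps is the
metric. The kernel and cost are deliberately fixed: no hyperparameter is
tuned, which is why the cross-validation fold/repeat settings recorded in
`shift_params()` do not influence the result and no CV loop is run inside
the bootstrap — a CV that tunes nothing cannot change the held-out
accuracy, and omitting it cuts runtime by an order of magnitude. Groups
with fewer than `min_cells_per_group` (default 10) cells are skipped with a
recorded reason rather than producing unstable accuracies.

**Subsampled DEG count** (`subsample_deg_count()`). Differential-expression
counts grow mechanically with cell number, so each of `n_permutations`
rounds first subsamples both conditions to at most `subsample_n` cells
(default 100; a condition at or below the cap is used whole — with both
conditions at the cap every round is identical and the metric is exact
rather than stochastic). Each round runs the filtered Wilcoxon test below
and records Bonferroni-adjusted p-values, with genes failing the filters in
that round set to p = 1. Per gene, rounds are combined with the Tippett
minimum-p rule, `1 − (1 − min p)^k` — the distribution function of the
minimum of k independent uniforms — and the metric is the number of genes
whose combined p falls below `alpha`. Only the per-gene minimum needs to be
tracked across rounds, which keeps memory flat.

**Consensus** (`consensus_rank()`, `sensitivity_report()`). Within each
tissue × timepoint stratum, each method ranks cell types descending by its
statistic (log fold change versus the null, median accuracy, DEG count),
rank 1 being the most perturbed; ties receive average ranks; the consensus
is the unweighted mean of the three ranks. A cell type skipped by any
method is excluded from all three, so every method ranks the same set.

## Differential expression and downstream calls

`wilcoxon_de()` implements the two-sided Wilcoxon rank-sum test with the
two standard pre-filters: a gene must be expressed (value > 0) in at least
10% of the cells of one group, and show at least 0.25 absolute log fold
change, computed as `ln((mean(expm1 x₁) + ε) / (mean(expm1 x₂) + ε))` with
ε = 10⁻⁹ — the de-logged-means convention of the single-cell software
family this analysis style comes from (the alternative, difference of mean
log values, is smaller in magnitude and would gate more genes). Filters are
applied *before* testing, and the Bonferroni family is the set of genes
actually tested. The p-value uses exact enumeration (`pwilcox`) when both
groups have at most 25 cells and the gene has no ties, and otherwise the
normal approximation with tie and continuity correction; the implementation
is vectorised over genes because the subsampled DEG metric calls it
thousands of times, and is tested row-by-row against `stats::wilcox.test`.

`conserved_markers()` re-uses the same test for one-cluster-versus-rest
comparisons inside each timepoint × condition stratum and combines strata
per gene with the Tippett rule (genes filtered out of any stratum are
dropped, not imputed; direction must agree across strata).
`reversed_genes()` intersects two DE tables — perturbed vs control, treated
vs perturbed — and returns genes significant in both with opposite
fold-change signs, the signature of a treatment that pushes expression back
toward control. `fisher_enrichment()` is a one-sided (greater) Fisher's
exact test of DEG overlap per gene set against the expressed-gene universe,
with Benjamini–Hochberg correction across sets.

## Ligand–receptor coordination

`lr_interaction_test()` scores an ordered cluster pair (A, B) and a
ligand–receptor pair by the mean of A's mean ligand expression and B's mean
receptor expression (the mean-of-means combiner). Pairs are tested only
when the ligand is expressed in strictly more than 10% of A's cells and the
receptor in strictly more than 10% of B's cells. The null shuffles all
cluster labels jointly (sizes preserved) and recomputes every score, with
the permutations shared across pairs for efficiency; p-values use the
add-one estimator. Counts of significant pairs per tile threshold the raw
permutation p at `alpha` with no cross-pair multiplicity correction — that
matches the interaction-counting convention this analysis follows, and the
detail table carries the p-values for anyone who prefers to correct.
Because tests are directional, both the ordered count matrix and its
symmetrized sum are returned; a strong boost of a ligand in one cluster can
legitimately light up additional tiles that share that cluster, since the
permutation null destroys all cluster structure at once.

## Batch-mixing QC

`batch_mixing_test()` is a kNN-based acceptance test run separately per
cell type (pooling cell types confounds batch composition with cell-type
frequency differences). On Euclidean distances over log-normalized
expression, each cell's neighbourhood — itself plus its k − 1 nearest
neighbours, with k defaulting to max(10, ⌈0.25 n⌉) since the appropriate
neighbourhood scale is data-dependent — is compared to the global batch
proportions with a chi-squared goodness-of-fit test at α = 0.05. Each of
`n_runs` (default 100) runs samples 10% of the cells and records the
rejection fraction; the acceptance rate is the mean of one minus the
rejection rate, and rates above 0.75 are flagged well mixed. A single batch
has zero degrees of freedom and acceptance exactly 1. Batches whose
expected neighbourhood count falls below 1 are merged smallest-first so the
chi-squared approximation stays usable. Cell types with fewer than 15 cells
are skipped.

## The synthetic generator and what it does (not) show

`generate_dataset()` draws gene-wise negative-binomial counts with a shared
dispersion (size 2 by default), per-gene baseline means log-normal
(meanlog −1, sdlog 1 — about 0.6 UMIs per gene per cell, i.e. a shallow
droplet library), a per-cell log-normal library-size factor (sd 0.3), 13
mitochondrial genes with means tuned to a 5% expected mitochondrial
fraction, and two batches. The perturbation is planted per cell type as a
fraction of DE genes shifted by ± a natural-log fold change (half up, half
down by default); the product `fraction_de × |log fc|` is the recorded true
effect size. Defaults fix a four-type design at 150 cells per type per
condition and 2000 genes with effect sizes 0 / 0.3 / 0.6 / 0.8, a strictly
ordered ladder the consensus rank should recover. Batch effects add a log
shift to a 10% gene subset in later batches; ligand–receptor structure is
planted by boosting a ligand's mean in one type and its receptor's in
another. Everything is deterministic given the seed.

The generator emulates the statistical structure the metrics rely on —
overdispersed counts, library-size variation, planted shifts of known size
— but not ambient RNA, doublets, dropout beyond what the NB implies,
cell-type-specific dispersions, or correlated gene programs. Tests passing
on it show the statistics are calibrated and recover planted orderings; they
do not certify behaviour on any particular real dataset.

## Numerical and design choices

* Empirical p-values always use the add-one estimator; they can never be 0
  and are bounded below by 1/(permutations + 1).
* Zero-variance genes z-score to 0; constant expression gives observed
  distance 0 and empirical p 1.
* Tie handling in ranking is average-rank throughout.
* The Euclidean null permutes condition labels with group sizes preserved —
  one specific reading of "randomly sampled cells"; it keeps the null
  exchangeable with the observed statistic and is the choice this package
  fixes and documents.
* Ranking uses the log fold change versus the null rather than the raw
  distance, because the raw distance scales with cell numbers; both are
  reported.
* Sub-seeds for each stochastic stage are derived from the master seed by a
  stable hash of the stage and cell-type labels, so per-component results
  do not depend on execution order.
* Problem sizes in the shipped validation suite are deliberate choices
  balancing statistical resolution against desk-scale runtimes: type-I
  calibration of the Euclidean test uses 400 single-type replicates at 100
  genes × 60 cells with 100 permutations; the ligand–receptor null rate
  pools ~1900 gated tests over 8 independent datasets (independent datasets
  decorrelate the shared-permutation null); parameter recovery runs 20
  replicates of the 4-type ladder at 500 genes, 80 cells per type per
  condition, 80 permutations, 30 bootstraps and 30 subsample rounds. The
  batch-separation scenario uses deeper libraries (meanlog 1, size 10) and
  a 0.3 gene fraction so the injected effect produces genuinely pure
  neighbourhoods — boosting half the library instead mostly cancels under
  per-cell normalization.

## Known limitations

* Transcriptome-shift metrics see only transcriptomic responses; a cell
  type responding post-transcriptionally will rank low.
* The SVM metric saturates: once conditions are fully separable, median
  accuracy is 1 regardless of effect size, and very strong effects become
  indistinguishable (ties are handled by average ranks).
* The DEG-count metric depends on the pre-filter thresholds; lowering the
  fold-change gate inflates counts for abundant types.
* Cluster labels are inputs: mislabelled cells blur all three metrics
  toward the null.
* The ligand–receptor test counts co-expression, not signalling; it cannot
  distinguish an interaction from two independently elevated genes.
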
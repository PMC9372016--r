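# scshift

Ranking cell-type sensitivity to a perturbation in single-cell RNA-seq, with
the supporting differential-expression, cell–cell coordination and
batch-mixing analyses.

## The problem

In a two-condition single-cell experiment (perturbed vs control animals,
cell-type labels already assigned), cell types differ widely in how strongly
their transcriptomes respond. Any single measure of that response is
confounded by cell abundance, depth and baseline heterogeneity, so `scshift`
scores every cell type with three complementary resampling metrics and
aggregates them:

1. **Euclidean shift** — the distance between the per-condition mean
   z-score vectors ("representative cells") over the top 1000 most highly
   expressed genes, against a condition-label permutation null. Reported as
   log2(observed / null mean) with an add-one empirical p-value,
   Bonferroni-corrected across cell types within a tissue × timepoint
   stratum.
2. **Classifier accuracy** — median held-out accuracy of a linear SVM
   (cost 1) predicting condition labels over 1000 stratified 70/30
   bootstrap splits.
3. **Subsampled DEG count** — the number of genes significant after
   Tippett minimum-p combination, `1 − (1 − min p)^k`, of
   Bonferroni-adjusted Wilcoxon rank-sum p-values across 1000 rounds in
   which each condition is subsampled to ≤100 cells (removing the
   cell-count dependence of DEG counts).

Each method ranks cell types within a tissue × timepoint stratum (rank 1 =
most perturbed, average ranks for ties) and the **consensus rank** is their
equal-weight mean.

Around this core the package provides filtered Wilcoxon differential
expression (expressed in ≥10% of one group, ≥0.25 absolute log fold
change, Bonferroni over tested genes), conserved cluster markers across
strata, treatment-reversed genes (significant in both perturbed-vs-control
and treated-vs-perturbed with opposite signs), Fisher's exact pathway
enrichment with BH correction, a CellPhoneDB-style ligand–receptor
permutation test with a >10% expression gate, a kNN chi-squared
batch-mixing acceptance test (acceptance > 0.75 = well mixed), and a
negative-binomial synthetic-data generator with planted ground truth that
makes the whole pipeline testable offline.

## Worked example

Generate a four-cell-type dataset whose planted per-type effect sizes
(fraction of DE genes × log fold change) form the ladder 0 / 0.3 / 0.6 /
0.8, then rank the types:

```r
library(scshift)

ds     <- generate_dataset(synth_config(n_cell_types = 4,
                                        cells_per_type_per_condition = 80,
                                        n_genes = 500, seed = 42))
f      <- filter_cells(ds$counts, qc_params(min_genes = 100))
expr   <- normalize_counts(f$counts)
ann    <- ds$annotation[ds$annotation$cell_id %in% colnames(expr), ]
params <- shift_params(top_n_genes = 200, n_permutations = 100,
                       n_bootstraps = 50, subsample_n = 50, seed = 7)
report <- sensitivity_report(expr, ann, params)
report[, c("cell_type", "ed_stat", "svm_stat", "deg_stat",
           "ed_rank", "svm_rank", "deg_rank", "avg_rank")]
#>   cell_type   ed_stat svm_stat deg_stat ed_rank svm_rank deg_rank avg_rank
#> 1     type4  2.215897    1.000      126       1        2        1     1.33
#> 2     type3  2.110283    1.000       95       2        2        2     2.00
#> 3     type2  1.626302    1.000       49       3        2        3     2.67
#> 4     type1 -0.000692    0.479        0       4        4        4     4.00
```

The consensus recovers the planted ordering exactly: type4 (largest true
effect) ranks first on the Euclidean log fold change (2.22 doublings above
the permutation null) and the DEG count (126 significant genes), while the
unperturbed type1 sits at chance-level classifier accuracy (0.479), a
Euclidean shift indistinguishable from its null (−0.0007), and zero DEGs.
The SVM column also shows the metric's known saturation — three perturbed
types all reach accuracy 1.000 and share the average rank 2 — which is
exactly why three metrics are combined.

`run_pipeline(analysis_config(...))` chains the stages (QC → sensitivity →
DE/reversal/enrichment → ligand–receptor → batch QC) from one seeded
configuration and writes TSV reports plus a JSON manifest;
`inst/cli/scshift.R` is a thin command-line wrapper over the same
functions.

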
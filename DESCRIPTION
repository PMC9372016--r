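Package: scshift
Title: Cell-Type Sensitivity Ranking and Coordination Analysis for
    Perturbed Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks cell types by their transcriptomic sensitivity to a
    perturbation using three complementary resampling metrics -- a
    permutation-null Euclidean distance between condition-representative
    cells, bootstrapped held-out accuracy of a linear support vector
    machine, and a subsampled Wilcoxon differential-expression count with
    Tippett minimum-p meta-analysis -- aggregated into an equal-weight
    consensus rank per tissue and timepoint. Also provides Wilcoxon
    rank-sum differential expression with expression-fraction and
    fold-change pre-filters, conserved cluster-marker meta-testing,
    detection of treatment-reversed genes, Fisher's exact pathway
    enrichment, a ligand-receptor co-expression permutation test between
    cell-type pairs, a k-nearest-neighbour batch-mixing acceptance test,
    and a negative-binomial synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    matrixStats,
    e1071,
    FNN,
    jsonlite,
    yaml,
    rlang,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
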
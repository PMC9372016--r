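test_that("top expressed genes follow mean expression with id tie-break", {
  e <- make_counts(matrix(c(5, 1, 3, 5, 1, 3), 3, 2), genes = c("gB", "gC", "gA"))
  expect_identical(top_expressed_genes(e, colnames(e), 2), c("gB", "gA"))
  expect_identical(top_expressed_genes(e, colnames(e), 10),
                   c("gB", "gA", "gC"))
  tied <- make_counts(matrix(2, 2, 3), genes = c("gZ", "gA"))
  expect_identical(top_expressed_genes(tied, colnames(tied), 2),
                   c("gA", "gZ"))
})

test_that("top expressed genes agree with a brute-force sort of row means", {
  e <- random_expr(200, 40, seed = 6)
  got <- top_expressed_genes(e, colnames(e), 50)
  means <- rowMeans(as.matrix(e))
  expected <- names(sort(means, decreasing = TRUE))[1:50]
  # brute force ignores ties (values are continuous so none occur)
  expect_identical(got, expected)
})

test_that("z-scores use the sample sd and zero out constant genes", {
  x <- make_counts(matrix(c(1, 2, 3), 1, 3, byrow = TRUE), genes = "g1")
  expect_equal(unname(zscore_genes(x)[1, ]), c(-1, 0, 1))
  const <- make_counts(matrix(4, 1, 5), genes = "g1")
  expect_equal(unname(zscore_genes(const)[1, ]), rep(0, 5))
  expect_error(zscore_genes(make_counts(matrix(1, 2, 1))), "2 cells")
})

test_that("z-score rows are standardized or identically zero", {
  z <- zscore_genes(random_expr(50, 30, seed = 2))
  m <- rowMeans(z)
  s <- matrixStats::rowSds(z)
  expect_true(all(abs(m) < 1e-10))
  expect_true(all(abs(s - 1) < 1e-10 | s == 0))
})

test_that("euclidean observed distance matches a brute-force reference", {
  set.seed(14)
  for (rep in 1:5) {
    e <- random_expr(30, 20, seed = rep)
    ann <- two_group_annotation(colnames(e), 10)
    p <- shift_params(top_n_genes = 30, n_permutations = 20,
                      min_cells_per_group = 5, seed = rep)
    res <- euclidean_shift(e, ann, "typeA", p)
    # straight-line reference: z-score manually, mean per group, root of
    # the summed squared differences
    x <- as.matrix(e)
    z <- t(apply(x, 1, function(v) {
      s <- sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }))
    d <- 0
    for (g in seq_len(nrow(z))) {
      d <- d + (mean(z[g, 1:10]) - mean(z[g, 11:20]))^2
    }
    expect_equal(res$observed_distance, sqrt(d), tolerance = 1e-10)
  }
})

test_that("euclidean statistic is invariant to gene order and group labels", {
  e <- random_expr(40, 24, seed = 8)
  ann <- two_group_annotation(colnames(e), 12)
  p <- shift_params(top_n_genes = 40, n_permutations = 10,
                    min_cells_per_group = 5, seed = 1)
  base <- euclidean_shift(e, ann, "typeA", p)
  shuffled <- e[sample(nrow(e)), ]
  expect_equal(euclidean_shift(shuffled, ann, "typeA", p)$observed_distance,
               base$observed_distance)
  flipped <- euclidean_shift(e, ann, "typeA", p,
                             conditions = c("perturbed", "control"))
  expect_equal(flipped$observed_distance, base$observed_distance)
})

test_that("constant expression gives distance 0 and empirical p of 1", {
  e <- make_counts(matrix(3, 20, 30))
  ann <- two_group_annotation(colnames(e), 15)
  p <- shift_params(top_n_genes = 20, n_permutations = 50,
                    min_cells_per_group = 5, seed = 2)
  res <- euclidean_shift(e, ann, "typeA", p)
  expect_equal(res$observed_distance, 0)
  expect_equal(res$p_empirical, 1)
})

test_that("empirical p respects the add-one floor and Bonferroni ordering", {
  ds <- generate_dataset(synth_config(n_cell_types = 2,
                                      cells_per_type_per_condition = 30,
                                      n_genes = 150,
                                      fraction_de = c(0, 0.4), seed = 3))
  e <- normalize_counts(ds$counts)
  p <- shift_params(top_n_genes = 100, n_permutations = 40,
                    min_cells_per_group = 5, seed = 4)
  res <- euclidean_shift_all(e, ds$annotation, p)
  expect_true(all(res$p_empirical >= 1 / 41))
  expect_true(all(res$p_adjusted >= res$p_empirical))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("groups below the minimum size are skipped with a reason", {
  e <- random_expr(10, 15, seed = 1)
  ann <- two_group_annotation(colnames(e), 9)   # 9 vs 6 cells
  p <- shift_params(min_cells_per_group = 10)
  expect_true(euclidean_shift(e, ann, "typeA", p)$skipped)
  s <- svm_shift(e, ann, "typeA", p)
  expect_true(s$skipped)
  expect_match(s$reason, "min_cells")
  expect_true(subsample_deg_count(e, ann, "typeA", p)$skipped)
})

test_that("svm accuracy is 1 on a separable toy", {
  x <- matrix(c(rep(0, 15), rep(10, 15)), 1, 30,
              dimnames = list("g1", sprintf("c%02d", 1:30)))
  e <- make_counts(x, genes = "g1", cells = colnames(x))
  ann <- two_group_annotation(colnames(e), 15)
  p <- shift_params(top_n_genes = 1, n_bootstraps = 20,
                    min_cells_per_group = 10, seed = 11)
  s <- svm_shift(e, ann, "typeA", p)
  expect_equal(s$median_accuracy, 1.0)
  expect_length(s$accuracies, 20)
  expect_equal(s$median_accuracy, median(s$accuracies))
})

test_that("tippett meta-p matches its closed form and boundary cases", {
  expect_equal(tippett_meta_p(0.2), 0.2)
  expect_equal(tippett_meta_p(c(0.01, 0.5, 0.9)), 1 - 0.99^3)
  expect_equal(tippett_meta_p(c(1, 1, 1)), 1)
  expect_error(tippett_meta_p(numeric(0)), "empty")
  expect_error(tippett_meta_p(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(tippett_meta_p(1.2))
})

test_that("tippett meta-p is monotone nonincreasing in the minimum p", {
  ps <- seq(0.01, 0.99, length.out = 50)
  out <- vapply(ps, function(p) tippett_meta_p(c(p, 0.995), k = 2),
                numeric(1))
  expect_true(all(diff(out) >= 0))
})

test_that("subsampling is a no-op when both conditions are at or below the cap", {
  ds <- generate_dataset(synth_config(n_cell_types = 1,
                                      cells_per_type_per_condition = 40,
                                      n_genes = 120, fraction_de = 0.3,
                                      effect_log_fc = 2, seed = 17))
  e <- normalize_counts(ds$counts)
  p <- shift_params(top_n_genes = 120, n_permutations = 5, subsample_n = 100,
                    min_cells_per_group = 10, alpha = 0.05, seed = 9)
  res <- subsample_deg_count(e, ds$annotation, "type1", p)
  # with no subsampling every round is identical: meta_p must equal the
  # closed form applied to a single direct run of the DE test
  grp <- split(ds$annotation$cell_id, ds$annotation$condition)
  de <- wilcoxon_de(e, grp$control, grp$perturbed, deg_params())
  single <- setNames(rep(1, nrow(e)), rownames(e))
  single[de$gene] <- de$p_adjusted
  expect_equal(res$meta_p, 1 - (1 - single)^5, tolerance = 1e-12)
  expect_equal(res$n_significant, sum(res$meta_p < 0.05))
})

test_that("consensus rank reproduces printed worked examples and handles ties", {
  cons <- consensus_rank(ed = c(a = 3, b = 2, c = 1),
                         svm = c(a = 0.9, b = 0.5, c = 0.7),
                         deg = c(a = 50, b = 10, c = 5))
  expect_equal(cons$avg_rank[cons$cell_type == "a"], 1)
  # ranks (3,1,1) -> 1.67 and (1,1,1) -> 1.00 at 2 d.p.
  expect_equal(round(mean(c(3, 1, 1)), 2), 1.67)
  expect_equal(round(mean(c(1, 1, 1)), 2), 1.00)
  tied <- consensus_rank(ed = c(a = 5, b = 5, c = 1),
                         svm = c(a = 1, b = 2, c = 3),
                         deg = c(a = 1, b = 2, c = 3))
  expect_equal(tied$ed_rank[match(c("a", "b"), tied$cell_type)],
               c(1.5, 1.5))
  expect_error(consensus_rank(ed = c(a = 1), svm = c(b = 1), deg = c(a = 1)),
               "differ")
})

test_that("per-method ranks are a permutation of 1..K and avg_rank in range", {
  set.seed(20)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    nm <- paste0("t", seq_len(k))
    cons <- consensus_rank(ed = setNames(rnorm(k), nm),
                           svm = setNames(runif(k), nm),
                           deg = setNames(rpois(k, 20), nm))
    expect_equal(sort(cons$ed_rank), seq_len(k))
    expect_true(all(cons$avg_rank >= 1 & cons$avg_rank <= k))
    expect_false(is.unsorted(cons$avg_rank))
  }
})
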
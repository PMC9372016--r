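test_that("vectorised rank-sum p-values agree with stats::wilcox.test", {
  set.seed(31)
  # continuous data, small n: exact branch
  x <- matrix(rnorm(20 * 16), 20, 16)
  p <- scshift:::rank_sum_test(x, n1 = 8)
  ref <- apply(x, 1, function(v) wilcox.test(v[1:8], v[9:16])$p.value)
  expect_equal(p, unname(ref), tolerance = 1e-12)
  # tied data: normal approximation with tie + continuity correction
  xt <- matrix(rpois(30 * 40, 1), 30, 40)
  pt <- scshift:::rank_sum_test(xt, n1 = 15)
  reft <- apply(xt, 1, function(v) {
    suppressWarnings(wilcox.test(v[1:15], v[16:40])$p.value)
  })
  expect_equal(pt, unname(reft), tolerance = 1e-12)
  # large n, continuous: approximation branch
  xl <- matrix(rnorm(10 * 80), 10, 80)
  pl <- scshift:::rank_sum_test(xl, n1 = 30)
  refl <- apply(xl, 1, function(v) {
    wilcox.test(v[1:30], v[31:80], exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(pl, unname(refl), tolerance = 1e-12)
})

test_that("the 4-vs-4 worked case gives the exact enumeration p of 2/70", {
  e <- make_counts(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 1, 8), genes = "g1")
  d <- wilcoxon_de(e, colnames(e)[1:4], colnames(e)[5:8],
                   deg_params(min_expressed_fraction = 0,
                              min_abs_log_fc = 0))
  expect_equal(d$p_raw, 2 / 70, tolerance = 1e-12)
})

test_that("genes below the expression-fraction or fold-change gates are not tested", {
  set.seed(4)
  m <- matrix(0, 3, 40, dimnames = list(c("rare", "flat", "de"),
                                        sprintf("c%02d", 1:40)))
  m["rare", c(1, 21)] <- 5                       # 5% expressed in each group
  m["flat", ] <- rep(c(1.0, 1.1), 20)            # tiny log fold change
  m["de", 1:20] <- 3                             # strong group-1 signal
  e <- make_counts(m, genes = rownames(m), cells = colnames(m))
  d <- wilcoxon_de(e, colnames(e)[1:20], colnames(e)[21:40], deg_params())
  expect_false("rare" %in% d$gene)
  expect_false("flat" %in% d$gene)
  expect_true("de" %in% d$gene)
  # Bonferroni denominator = genes tested (here a single gene)
  expect_equal(d$p_adjusted, d$p_raw)
})

test_that("swapping group labels flips the fold change and keeps p", {
  e <- random_expr(40, 30, seed = 12)
  p0 <- deg_params(min_expressed_fraction = 0, min_abs_log_fc = 0)
  a <- wilcoxon_de(e, colnames(e)[1:15], colnames(e)[16:30], p0)
  b <- wilcoxon_de(e, colnames(e)[16:30], colnames(e)[1:15], p0)
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$log_fc, -b$log_fc)
  expect_equal(a$p_raw, b$p_raw)
})

test_that("overlapping groups are an error", {
  e <- random_expr(5, 10, seed = 1)
  expect_error(wilcoxon_de(e, colnames(e)[1:5], colnames(e)[5:10]),
               "overlap")
})

test_that("conserved markers find a planted marker and reject flat genes", {
  set.seed(41)
  n_per <- 20  # cells per cluster per stratum
  cells <- sprintf("c%03d", 1:(n_per * 2 * 2))
  ann <- data.frame(cell_id = cells, sample_id = "s",
                    tissue = "t",
                    timepoint = rep(c("24h", "7d"), each = n_per * 2),
                    condition = "control",
                    batch = "b",
                    cell_type = rep(rep(c("X", "Y"), each = n_per), 2),
                    stringsAsFactors = FALSE)
  m <- matrix(abs(rnorm(30 * length(cells), 1)), 30, length(cells),
              dimnames = list(sprintf("g%02d", 1:30), cells))
  in_x <- ann$cell_type == "X"
  m["g01", in_x] <- 5          # marker: high in X in every stratum
  m["g02", ] <- 1              # identical everywhere
  m["g03", !in_x] <- 1
  m["g03", in_x] <- log1p(expm1(1) * exp(0.2))   # exactly 0.2 lfc: gated out
  e <- make_counts(m, genes = rownames(m), cells = cells)
  mk <- conserved_markers(e, ann, "X", min_cells = 10)
  expect_true("g01" %in% mk$gene)
  expect_lt(mk$p_adjusted[mk$gene == "g01"], 0.05)
  expect_false("g02" %in% mk$gene)
  expect_false("g03" %in% mk$gene)
})

test_that("conserved markers need at least two usable strata", {
  e <- random_expr(10, 20, seed = 2)
  ann <- two_group_annotation(colnames(e), 10)
  ann$cell_type <- rep(c("X", "Y"), each = 10)
  ann$condition <- "control"
  expect_error(suppressWarnings(
    conserved_markers(e, ann, "X", strata_cols = "timepoint",
                      min_cells = 30)),
    "2 usable strata")
})

test_that("reversal keeps exactly the both-significant opposite-sign genes", {
  a <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  log_fc = c(0.5, 0.6, -0.4, 0.8),
                  p_adjusted = c(0.001, 0.02, 0.01, 0.3))
  b <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  log_fc = c(-0.4, 0.5, 0.3, -0.9),
                  p_adjusted = c(0.01, 0.01, 0.04, 0.001))
  rv <- reversed_genes(a, b)
  # g1: opposite signs, both significant; g2 same sign; g4 not significant
  # in the first table; g3 opposite (negative then positive) and significant
  expect_setequal(rv$gene, c("g1", "g3"))
  expect_equal(rv$log_fc_perturbed[rv$gene == "g1"], 0.5)
  expect_equal(rv$log_fc_treated[rv$gene == "g1"], -0.4)
})

test_that("reversal is symmetric as a gene set", {
  set.seed(7)
  a <- data.frame(gene = sprintf("g%d", 1:50), log_fc = rnorm(50),
                  p_adjusted = runif(50, 0, 0.2))
  b <- data.frame(gene = sprintf("g%d", 1:50), log_fc = rnorm(50),
                  p_adjusted = runif(50, 0, 0.2))
  expect_setequal(reversed_genes(a, b)$gene, reversed_genes(b, a)$gene)
})

test_that("fisher enrichment matches a hypergeometric tail oracle", {
  universe <- sprintf("u%03d", 1:100)
  query <- universe[1:10]
  gset <- universe[c(1:8, 50:61)]   # set of 20, overlap 8
  res <- fisher_enrichment(query, list(s = gset), universe)
  # independent summation of the hypergeometric upper tail P(X >= 8)
  oracle <- sum(vapply(8:10, function(i) {
    choose(20, i) * choose(80, 10 - i) / choose(100, 10)
  }, numeric(1)))
  expect_equal(res$p_raw, oracle, tolerance = 1e-12)
  expect_equal(res$overlap, 8)
})

test_that("fisher enrichment boundary cases", {
  universe <- sprintf("u%02d", 1:30)
  none <- fisher_enrichment(universe[1:5], list(s = universe[6:10]),
                            universe)
  expect_equal(none$p_raw, 1)
  forced <- fisher_enrichment(universe, list(s = universe), universe)
  expect_equal(forced$p_raw, 1)
  expect_error(fisher_enrichment("g", list(s = "g"), character(0)),
               "universe")
})

test_that("BH correction over sets is monotone after the step-up", {
  set.seed(9)
  universe <- sprintf("u%03d", 1:200)
  sets <- lapply(1:20, function(i) sample(universe, 30))
  names(sets) <- paste0("s", 1:20)
  res <- fisher_enrichment(sample(universe, 25), sets, universe)
  expect_true(all(diff(res$fdr[order(res$p_raw)]) >= -1e-12))
  expect_true(all(res$fdr >= res$p_raw - 1e-12))
})
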
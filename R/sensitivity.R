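#' Parameters for the transcriptome-shift metrics
#'
#' Defaults follow the protocol of the three resampling metrics: the top
#' 1000 most highly expressed genes per cell type, 1000 permutations for the
#' Euclidean-distance null, 1000 bootstraps of a 70/30 split for the
#' classifier, subsampling to 100 cells per condition for the DEG count, and
#' a minimum of 10 cells per group.
#'
#' @param top_n_genes Genes ranked by mean expression kept per cell type.
#' @param n_permutations Label permutations for the Euclidean null and
#'   subsample rounds for the DEG metric.
#' @param n_bootstraps Bootstrap train/test splits for the classifier.
#' @param train_fraction Fraction of cells in the training split.
#' @param cv_folds,cv_repeats Cross-validation protocol recorded with the
#'   classifier; no hyperparameter is tuned (see the methods vignette).
#' @param subsample_n Per-condition cell cap for the subsampled DEG metric.
#' @param min_cells_per_group Groups below this size are skipped.
#' @param alpha Significance threshold for the DEG count.
#' @param log_base Base of the fold-change reported against the null mean.
#' @param seed Optional seed; per-cell-type sub-seeds are derived from it.
#' @return A list of class `shift_params`.
#' @export
shift_params <- function(top_n_genes = 1000, n_permutations = 1000,
                         n_bootstraps = 1000, train_fraction = 0.7,
                         cv_folds = 10, cv_repeats = 3,
                         subsample_n = 100, min_cells_per_group = 10,
                         alpha = 0.05, log_base = 2, seed = NULL) {
  stopifnot(top_n_genes >= 1, n_permutations >= 1, n_bootstraps >= 1,
            train_fraction > 0, train_fraction < 1,
            subsample_n >= 1, min_cells_per_group >= 2,
            alpha > 0, alpha < 1)
  structure(list(top_n_genes = as.integer(top_n_genes),
                 n_permutations = as.integer(n_permutations),
                 n_bootstraps = as.integer(n_bootstraps),
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 subsample_n = as.integer(subsample_n),
                 min_cells_per_group = as.integer(min_cells_per_group),
                 alpha = alpha, log_base = log_base, seed = seed),
            class = "shift_params")
}

#' Top expressed genes over a set of cells
#'
#' Genes sorted by mean log-normalized expression over the given cells (both
#' conditions pooled), descending; ties broken by gene id. Returns
#' `min(n, available)` genes.
#'
#' @param expr Genes x cells expression matrix.
#' @param cells Cell ids or column indices.
#' @param n Number of genes to return.
#' @return Character vector of gene ids.
#' @export
top_expressed_genes <- function(expr, cells, n) {
  sub <- expr[, cells, drop = FALSE]
  if (ncol(sub) == 0) stop("no cells selected")
  means <- Matrix::rowMeans(sub)
  ord <- order(-means, rownames(expr))
  rownames(expr)[ord[seq_len(min(n, nrow(expr)))]]
}

#' Per-gene z-scores across the cells of one cell type
#'
#' Each gene is centred and scaled by its sample (n-1) standard deviation
#' over the pooled cells; zero-variance genes map to all-zero rows.
#'
#' @param x Genes x cells matrix (one cell type, conditions pooled).
#' @return A dense matrix of z-scores with the same dimnames.
#' @export
zscore_genes <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("z-scores need at least 2 cells (sd undefined)")
  mu <- rowMeans(x)
  sd <- matrixStats::rowSds(x)
  z <- (x - mu) / sd
  z[sd == 0, ] <- 0
  z
}

skipped_record <- function(cell_type, n1, n2, reason) {
  data.frame(cell_type = cell_type, n_group1 = n1, n_group2 = n2,
             skipped = TRUE, reason = reason, stringsAsFactors = FALSE)
}

group_cells <- function(annotation, cell_type, conditions) {
  ann <- annotation[annotation$cell_type == cell_type &
                      annotation$condition %in% conditions, , drop = FALSE]
  split(ann$cell_id, factor(ann$condition, levels = conditions))
}

#' Euclidean transcriptome-shift statistic with a permutation null
#'
#' For one cell type, builds per-condition "representative cells" (mean
#' z-score vectors over the top expressed genes) and measures the Euclidean
#' distance between them. The null is the same distance under condition-label
#' permutations with group sizes preserved; gene selection and z-scores are
#' computed once on the pooled cells. The empirical p uses the add-one
#' estimator, so it is never 0.
#'
#' @param expr Genes x cells log-normalized expression matrix.
#' @param annotation Cell annotation data.frame.
#' @param cell_type Cell type to test.
#' @param params A [shift_params()].
#' @param conditions Length-2 character: the two condition labels compared.
#' @return One-row data.frame: observed distance, null mean and sd,
#'   `log_fc_vs_null` (log, default base 2, of observed over the null mean)
#'   and `p_empirical`; or a skipped record when a group is too small.
#' @export
euclidean_shift <- function(expr, annotation, cell_type,
                            params = shift_params(),
                            conditions = c("control", "perturbed")) {
  grp <- group_cells(annotation, cell_type, conditions)
  n1 <- length(grp[[1]]); n2 <- length(grp[[2]])
  if (min(n1, n2) < params$min_cells_per_group) {
    return(skipped_record(cell_type, n1, n2,
                          "fewer cells than min_cells_per_group"))
  }
  if (!is.null(params$seed)) set.seed(sub_seed(params$seed, "ed", cell_type))
  cells <- c(grp[[1]], grp[[2]])
  genes <- top_expressed_genes(expr, cells, params$top_n_genes)
  z <- zscore_genes(expr[genes, cells, drop = FALSE])
  is1 <- seq_along(cells) <= n1
  observed <- mean_vector_distance(z, is1)
  null <- replicate(params$n_permutations, {
    perm <- sample(is1)
    mean_vector_distance(z, perm)
  })
  p <- (1 + sum(null >= observed)) / (1 + params$n_permutations)
  data.frame(cell_type = cell_type, n_group1 = n1, n_group2 = n2,
             observed_distance = observed,
             null_mean = mean(null), null_sd = stats::sd(null),
             log_fc_vs_null = log(observed / mean(null), params$log_base),
             p_empirical = p, skipped = FALSE, reason = "",
             stringsAsFactors = FALSE)
}

mean_vector_distance <- function(z, in_group1) {
  d <- rowMeans(z[, in_group1, drop = FALSE]) -
    rowMeans(z[, !in_group1, drop = FALSE])
  sqrt(sum(d * d))
}

#' Euclidean shift for every cell type in a stratum
#'
#' Runs [euclidean_shift()] per cell type and Bonferroni-adjusts the
#' empirical p-values across the cell types actually tested (the
#' multiple-testing family is the stratum).
#'
#' @inheritParams euclidean_shift
#' @param cell_types Cell types to test; default all in the annotation.
#' @return data.frame with one row per cell type including `p_adjusted`.
#' @export
euclidean_shift_all <- function(expr, annotation, params = shift_params(),
                                conditions = c("control", "perturbed"),
                                cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- sort(unique(annotation$cell_type))
  res <- lapply(cell_types, function(ct) {
    euclidean_shift(expr, annotation, ct, params, conditions)
  })
  out <- do.call(rbind_fill, res)
  tested <- !out$skipped
  out$p_adjusted <- NA_real_
  out$p_adjusted[tested] <- pmin(1, out$p_empirical[tested] * sum(tested))
  out
}

#' Bootstrapped linear-SVM condition classifier accuracy
#'
#' For one cell type, repeatedly draws a stratified 70/30 train/test split,
#' fits a linear-kernel soft-margin SVM (cost 1) on the training cells over
#' the top expressed genes, and records held-out accuracy at predicting the
#' condition labels. Reports the accuracy vector and its median. Skipped when
#' either group has fewer than `min_cells_per_group` cells.
#'
#' @inheritParams euclidean_shift
#' @return A list of class `svm_shift`: `cell_type`, `accuracies`,
#'   `median_accuracy`, `skipped`, `reason`.
#' @export
svm_shift <- function(expr, annotation, cell_type, params = shift_params(),
                      conditions = c("control", "perturbed")) {
  grp <- group_cells(annotation, cell_type, conditions)
  n1 <- length(grp[[1]]); n2 <- length(grp[[2]])
  if (min(n1, n2) < params$min_cells_per_group) {
    return(structure(list(cell_type = cell_type, accuracies = numeric(0),
                          median_accuracy = NA_real_, skipped = TRUE,
                          reason = "fewer cells than min_cells_per_group"),
                     class = "svm_shift"))
  }
  if (!is.null(params$seed)) set.seed(sub_seed(params$seed, "svm", cell_type))
  cells <- c(grp[[1]], grp[[2]])
  genes <- top_expressed_genes(expr, cells, params$top_n_genes)
  x <- t(as.matrix(expr[genes, cells, drop = FALSE]))
  y <- factor(rep(conditions, c(n1, n2)))
  idx1 <- which(y == conditions[1]); idx2 <- which(y == conditions[2])
  ntr1 <- max(1, round(params$train_fraction * n1))
  ntr2 <- max(1, round(params$train_fraction * n2))
  ntr1 <- min(ntr1, n1 - 1); ntr2 <- min(ntr2, n2 - 1)
  acc <- vapply(seq_len(params$n_bootstraps), function(b) {
    tr <- c(sample(idx1, ntr1), sample(idx2, ntr2))
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = 1, scale = FALSE)
    pred <- stats::predict(fit, x[-tr, , drop = FALSE])
    mean(pred == y[-tr])
  }, numeric(1))
  structure(list(cell_type = cell_type, accuracies = acc,
                 median_accuracy = stats::median(acc), skipped = FALSE,
                 reason = ""), class = "svm_shift")
}

#' Tippett minimum-p meta-analysis
#'
#' Combines k p-values as `1 - (1 - min(p))^k`, the probability that the
#' smallest of k independent uniform p-values is at most the observed
#' minimum.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param k Number of tests combined; defaults to `length(p)`.
#' @return The combined p-value.
#' @export
tippett_meta_p <- function(p, k = length(p)) {
  if (length(p) == 0) stop("tippett_meta_p: empty p-value list")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stopifnot(k >= 1)
  1 - (1 - min(p))^k
}

#' Subsampled differential-expression count
#'
#' For one cell type, each round subsamples both conditions to at most
#' `subsample_n` cells (a condition at or below the cap is used whole), runs
#' the Wilcoxon DE test with its expression-fraction and fold-change
#' pre-filters, and records each gene's Bonferroni-adjusted p (genes failing
#' the filters in that round count as p = 1). Per gene the rounds are
#' combined with the Tippett minimum-p over `n_permutations` rounds;
#' `n_significant` counts genes with meta p below `alpha`.
#'
#' @inheritParams euclidean_shift
#' @param deg_params A [deg_params()] passed to [wilcoxon_de()].
#' @return A list of class `subsample_deg`: `cell_type`, `meta_p` (named per
#'   gene), `n_significant`, `skipped`, `reason`.
#' @export
subsample_deg_count <- function(expr, annotation, cell_type,
                                params = shift_params(),
                                deg_params = scshift::deg_params(),
                                conditions = c("control", "perturbed")) {
  grp <- group_cells(annotation, cell_type, conditions)
  n1 <- length(grp[[1]]); n2 <- length(grp[[2]])
  if (min(n1, n2) < params$min_cells_per_group) {
    return(structure(list(cell_type = cell_type, meta_p = numeric(0),
                          n_significant = NA_integer_, skipped = TRUE,
                          reason = "fewer cells than min_cells_per_group"),
                     class = "subsample_deg"))
  }
  if (!is.null(params$seed)) set.seed(sub_seed(params$seed, "deg", cell_type))
  sub_expr <- as.matrix(expr[, c(grp[[1]], grp[[2]]), drop = FALSE])
  min_p <- stats::setNames(rep(1, nrow(expr)), rownames(expr))
  for (i in seq_len(params$n_permutations)) {
    c1 <- if (n1 > params$subsample_n) sample(grp[[1]], params$subsample_n) else grp[[1]]
    c2 <- if (n2 > params$subsample_n) sample(grp[[2]], params$subsample_n) else grp[[2]]
    de <- wilcoxon_de(sub_expr, c1, c2, deg_params)
    if (nrow(de)) {
      min_p[de$gene] <- pmin(min_p[de$gene], de$p_adjusted)
    }
  }
  meta_p <- 1 - (1 - min_p)^params$n_permutations
  structure(list(cell_type = cell_type, meta_p = meta_p,
                 n_significant = sum(meta_p < params$alpha),
                 skipped = FALSE, reason = ""),
            class = "subsample_deg")
}

#' Equal-weight consensus rank across the three shift metrics
#'
#' Ranks cell types per method (rank 1 = most perturbed: largest
#' Euclidean-shift log fold change vs null, largest median classifier
#' accuracy, largest subsampled DEG count), with ties given average ranks,
#' and averages the three ranks with equal weight.
#'
#' @param ed Named numeric vector of Euclidean-shift statistics per cell type.
#' @param svm Named numeric vector of median classifier accuracies.
#' @param deg Named numeric vector of significant-DEG counts.
#' @return data.frame sorted ascending by `avg_rank` with per-method ranks.
#' @export
consensus_rank <- function(ed, svm, deg) {
  types <- names(ed)
  if (is.null(types) || is.null(names(svm)) || is.null(names(deg))) {
    stop("all three statistic vectors must be named by cell type")
  }
  if (!setequal(types, names(svm)) || !setequal(types, names(deg))) {
    diff <- unique(c(setdiff(types, names(svm)), setdiff(names(svm), types),
                     setdiff(types, names(deg)), setdiff(names(deg), types)))
    stop("cell-type sets differ between methods: ",
         paste(diff, collapse = ", "))
  }
  svm <- svm[types]; deg <- deg[types]
  rank_desc <- function(x) rank(-x, ties.method = "average")
  out <- data.frame(cell_type = types,
                    ed_stat = unname(ed), svm_stat = unname(svm),
                    deg_stat = unname(deg),
                    ed_rank = rank_desc(ed), svm_rank = rank_desc(svm),
                    deg_rank = rank_desc(deg), stringsAsFactors = FALSE)
  out$avg_rank <- (out$ed_rank + out$svm_rank + out$deg_rank) / 3
  out[order(out$avg_rank, out$cell_type), , drop = FALSE]
}

#' Full sensitivity report over tissue-by-timepoint strata
#'
#' Runs the three shift metrics for every cell type within each tissue x
#' timepoint stratum, Bonferroni-adjusts the Euclidean empirical p within
#' the stratum, and aggregates per-method ranks into the consensus average
#' rank. Cell types skipped by any method (too few cells) are excluded from
#' all three rankings in that stratum.
#'
#' @inheritParams euclidean_shift
#' @param deg_params A [deg_params()] for the subsampled DEG metric.
#' @return data.frame with one row per (tissue, timepoint, cell_type):
#'   statistics, per-method ranks and `avg_rank`, sorted within stratum.
#' @export
sensitivity_report <- function(expr, annotation, params = shift_params(),
                               deg_params = scshift::deg_params(),
                               conditions = c("control", "perturbed")) {
  strata <- unique(annotation[, c("tissue", "timepoint"), drop = FALSE])
  out <- NULL
  for (s in seq_len(nrow(strata))) {
    ann_s <- annotation[annotation$tissue == strata$tissue[s] &
                          annotation$timepoint == strata$timepoint[s], ,
                        drop = FALSE]
    types <- sort(unique(ann_s$cell_type))
    ed <- euclidean_shift_all(expr, ann_s, params, conditions, types)
    svm <- lapply(types, function(ct) svm_shift(expr, ann_s, ct, params,
                                                conditions))
    deg <- lapply(types, function(ct) subsample_deg_count(expr, ann_s, ct,
                                                          params, deg_params,
                                                          conditions))
    keep <- !ed$skipped & !vapply(svm, `[[`, logical(1), "skipped") &
      !vapply(deg, `[[`, logical(1), "skipped")
    if (!any(keep)) next
    ed_stat <- stats::setNames(ed$log_fc_vs_null, ed$cell_type)[keep]
    svm_stat <- stats::setNames(
      vapply(svm, `[[`, numeric(1), "median_accuracy"), types)[keep]
    deg_stat <- stats::setNames(
      vapply(deg, function(d) as.numeric(d$n_significant), numeric(1)),
      types)[keep]
    cons <- consensus_rank(ed_stat, svm_stat, deg_stat)
    cons <- cbind(tissue = strata$tissue[s], timepoint = strata$timepoint[s],
                  cons,
                  ed_p_adjusted = stats::setNames(
                    ed$p_adjusted, ed$cell_type)[cons$cell_type])
    out <- if (is.null(out)) cons else rbind(out, cons)
  }
  rownames(out) <- NULL
  out
}

# rbind data.frames that may have different columns (skipped records)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, dfs)
}

# stable 32-bit sub-seed from a master seed and labels
sub_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(labels) * seq_along(utf8ToInt(labels)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
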
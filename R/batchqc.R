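#' k-nearest-neighbour batch-mixing acceptance test for one cell type
#'
#' Within the cells of one cell type, builds a k-nearest-neighbour graph on
#' Euclidean distance over the log-normalized expression, then repeatedly
#' samples a fraction of the cells and, for each sampled cell, compares the
#' batch-label composition of its neighbourhood (the cell itself plus its
#' k - 1 nearest neighbours) with the global batch proportions using a
#' chi-squared goodness-of-fit test at level `alpha`. A run's rejection rate
#' is the fraction of sampled cells rejecting; the acceptance rate is the
#' mean over runs of one minus the rejection rate. Acceptance above
#' `threshold` is called well mixed. With a single batch the test has zero
#' degrees of freedom, never rejects, and acceptance is 1.
#'
#' Batches whose expected neighbourhood count falls below 1 are merged with
#' the next-smallest batch before testing.
#'
#' @param expr Genes x cells log-normalized expression matrix.
#' @param annotation Cell annotation data.frame.
#' @param cell_type Cell type to test.
#' @param batch_col Annotation column holding the batch label.
#' @param k Neighbourhood size including the cell itself; default
#'   `max(10, ceiling(0.25 * n))`, capped at n.
#' @param n_runs Number of subsampling runs.
#' @param subsample_fraction Fraction of cells scored per run.
#' @param alpha Level of the per-cell chi-squared test.
#' @param min_cells Minimum cells of the type across batches.
#' @param threshold Acceptance rate above which batches are called well
#'   mixed.
#' @param seed Optional seed for the subsampling.
#' @return One-row data.frame: cell_type, n_cells, n_batches, k,
#'   acceptance_rate, n_runs, well_mixed, skipped, reason.
#' @export
batch_mixing_test <- function(expr, annotation, cell_type,
                              batch_col = "batch", k = NULL, n_runs = 100,
                              subsample_fraction = 0.10, alpha = 0.05,
                              min_cells = 15, threshold = 0.75,
                              seed = NULL) {
  ann <- annotation[annotation$cell_type == cell_type, , drop = FALSE]
  cells <- intersect(ann$cell_id, colnames(expr))
  n <- length(cells)
  if (n < min_cells) {
    return(data.frame(cell_type = cell_type, n_cells = n,
                      n_batches = NA_integer_, k = NA_integer_,
                      acceptance_rate = NA_real_, n_runs = n_runs,
                      well_mixed = NA, skipped = TRUE,
                      reason = "fewer cells than min_cells",
                      stringsAsFactors = FALSE))
  }
  batch <- ann[[batch_col]][match(cells, ann$cell_id)]
  batch <- factor(batch)
  batch <- droplevels(batch)
  if (is.null(k)) k <- max(10, ceiling(0.25 * n))
  k <- min(k, n)
  x <- t(as.matrix(expr[, cells, drop = FALSE]))

  result <- function(acc) {
    data.frame(cell_type = cell_type, n_cells = n,
               n_batches = nlevels(batch), k = k,
               acceptance_rate = acc, n_runs = n_runs,
               well_mixed = acc > threshold, skipped = FALSE, reason = "",
               stringsAsFactors = FALSE)
  }
  if (nlevels(batch) < 2) return(result(1.0))

  # global proportions; merge batches whose expected count in a size-k
  # neighbourhood is below 1 (merged smallest-first)
  repeat {
    prop <- table(batch) / n
    expected <- k * prop
    if (all(expected >= 1) || nlevels(batch) <= 2) break
    ord <- names(sort(table(batch)))
    merged <- paste(ord[1], ord[2], sep = "+")
    lv <- levels(batch)
    lv[lv %in% ord[1:2]] <- merged
    levels(batch) <- lv
    batch <- droplevels(batch)
  }
  if (nlevels(batch) < 2) return(result(1.0))
  prop <- as.numeric(table(batch)) / n
  b_int <- as.integer(batch)
  nb <- nlevels(batch)

  # neighbourhood = self + (k-1) nearest neighbours
  nn <- if (k > 1) {
    FNN::get.knn(x, k = k - 1)$nn.index
  } else {
    matrix(integer(0), nrow = n, ncol = 0)
  }
  hood_counts <- matrix(0L, n, nb)
  for (i in seq_len(n)) {
    idx <- c(i, nn[i, ])
    tab <- tabulate(b_int[idx], nbins = nb)
    hood_counts[i, ] <- tab
  }
  expected <- k * prop
  stat <- rowSums((hood_counts -
                     matrix(expected, n, nb, byrow = TRUE))^2 /
                    matrix(expected, n, nb, byrow = TRUE))
  p_cell <- stats::pchisq(stat, df = nb - 1, lower.tail = FALSE)

  if (!is.null(seed)) set.seed(seed)
  n_sample <- max(1, ceiling(subsample_fraction * n))
  rejection <- vapply(seq_len(n_runs), function(r) {
    idx <- sample.int(n, n_sample)
    mean(p_cell[idx] < alpha)
  }, numeric(1))
  result(mean(1 - rejection))
}

#' Batch-mixing acceptance for every cell type
#'
#' @inheritParams batch_mixing_test
#' @param cell_types Cell types to test; default all in the annotation.
#' @return data.frame, one row per cell type (see [batch_mixing_test()]).
#' @export
batch_mixing_all <- function(expr, annotation, batch_col = "batch",
                             cell_types = NULL, ...) {
  if (is.null(cell_types)) cell_types <- sort(unique(annotation$cell_type))
  out <- lapply(cell_types, function(ct) {
    batch_mixing_test(expr, annotation, ct, batch_col = batch_col, ...)
  })
  do.call(rbind, out)
}
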
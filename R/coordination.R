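#' Ligand-receptor co-expression permutation test between cell-type pairs
#'
#' For every ordered pair of cell types (A, B) and every ligand-receptor
#' pair, tests whether the co-expression score — the mean of cluster A's
#' mean ligand expression and cluster B's mean receptor expression on the
#' log-normalized scale — is larger than expected under a null built by
#' permuting the cluster labels of all cells (cluster sizes preserved, all
#' labels shuffled jointly). A pair is only tested for (A, B) when the
#' ligand is expressed (value > 0) in strictly more than `min_fraction` of
#' A's cells and the receptor in strictly more than `min_fraction` of B's
#' cells. The per-test p-value uses the add-one estimator, so it is never 0.
#'
#' Interactions are directional; the tile matrix is reported over ordered
#' pairs and additionally as the symmetrized sum. Per-tile counts threshold
#' the raw permutation p at `alpha` (no multiplicity correction across
#' pairs, matching the counting convention of CellPhoneDB-style analyses).
#'
#' @param expr Genes x cells log-normalized expression matrix.
#' @param annotation Cell annotation data.frame (uses `cell_id`,
#'   `cell_type`).
#' @param pairs data.frame with columns `ligand`, `receptor`; pairs whose
#'   genes are absent from the matrix are dropped with a warning.
#' @param n_permutations Cluster-label permutations (shared across pairs).
#' @param alpha Significance threshold for counting an interaction.
#' @param min_fraction Expression-fraction gate (strictly greater than).
#' @param min_cells Cell types with fewer cells are excluded.
#' @param seed Optional seed for the permutations.
#' @return A list of class `lr_result`: `detail` (pair, cluster_a,
#'   cluster_b, score, p), `matrix_ordered` (significant counts, rows =
#'   ligand cluster), `matrix_symmetric` (ordered + transpose), `n_tested`.
#' @export
lr_interaction_test <- function(expr, annotation, pairs,
                                n_permutations = 1000, alpha = 0.05,
                                min_fraction = 0.10, min_cells = 10,
                                seed = NULL) {
  stopifnot(n_permutations >= 100)
  ann <- annotation[match(colnames(expr), annotation$cell_id), , drop = FALSE]
  type_tab <- table(ann$cell_type)
  types <- sort(names(type_tab[type_tab >= min_cells]))
  if (length(types) < 2) stop("need at least 2 cell types with >= min_cells")
  keep_cells <- ann$cell_type %in% types
  expr <- expr[, keep_cells, drop = FALSE]
  labels <- factor(ann$cell_type[keep_cells], levels = types)

  present <- pairs$ligand %in% rownames(expr) &
    pairs$receptor %in% rownames(expr)
  if (any(!present)) {
    warning(sum(!present), " ligand-receptor pair(s) dropped: gene(s) not ",
            "in the expression matrix")
  }
  pairs <- pairs[present, , drop = FALSE]
  genes <- unique(c(pairs$ligand, pairs$receptor))
  x <- expr[genes, , drop = FALSE]

  # cluster sizes and per-cluster means / expressed fractions
  memb <- Matrix::sparseMatrix(i = seq_along(labels),
                               j = as.integer(labels),
                               x = 1, dims = c(length(labels), length(types)))
  sizes <- Matrix::colSums(memb)
  memb <- memb %*% Matrix::Diagonal(x = 1 / sizes)
  cl_mean <- as.matrix(x %*% memb)
  cl_frac <- as.matrix((x > 0) %*% memb)
  colnames(cl_mean) <- colnames(cl_frac) <- types

  # gated (pair, A, B) triples
  grid <- expand.grid(pair = seq_len(nrow(pairs)),
                      a = types, b = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  lig <- pairs$ligand[grid$pair]
  rec <- pairs$receptor[grid$pair]
  gate <- cl_frac[cbind(lig, grid$a)] > min_fraction &
    cl_frac[cbind(rec, grid$b)] > min_fraction
  grid <- grid[gate, , drop = FALSE]
  lig <- lig[gate]; rec <- rec[gate]
  empty <- matrix(0L, length(types), length(types),
                  dimnames = list(types, types))
  if (!nrow(grid)) {
    warning("no ligand-receptor pair passed the expression-fraction gate")
    return(structure(list(detail = data.frame(), matrix_ordered = empty,
                          matrix_symmetric = empty, n_tested = 0L),
                     class = "lr_result"))
  }
  observed <- (cl_mean[cbind(lig, grid$a)] + cl_mean[cbind(rec, grid$b)]) / 2

  if (!is.null(seed)) set.seed(seed)
  exceed <- integer(nrow(grid))
  for (p in seq_len(n_permutations)) {
    perm <- sample.int(length(labels))
    pm <- as.matrix(x[, perm, drop = FALSE] %*% memb)
    colnames(pm) <- types
    null_score <- (pm[cbind(lig, grid$a)] + pm[cbind(rec, grid$b)]) / 2
    exceed <- exceed + (null_score >= observed)
  }
  pval <- (1 + exceed) / (1 + n_permutations)

  detail <- data.frame(ligand = lig, receptor = rec,
                       cluster_a = grid$a, cluster_b = grid$b,
                       score = observed, p = pval,
                       significant = pval < alpha, stringsAsFactors = FALSE)
  rownames(detail) <- NULL
  sig <- detail[detail$significant, , drop = FALSE]
  mat <- empty
  if (nrow(sig)) {
    counts <- table(factor(sig$cluster_a, levels = types),
                    factor(sig$cluster_b, levels = types))
    mat <- empty + as.integer(counts)
    mat[] <- as.integer(counts)
  }
  structure(list(detail = detail,
                 matrix_ordered = mat,
                 matrix_symmetric = mat + t(mat),
                 n_tested = nrow(detail)),
            class = "lr_result")
}
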
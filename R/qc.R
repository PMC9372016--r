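#' Quality-control parameters for cell filtering
#'
#' @param min_genes Minimum number of detected genes (count > 0) per cell.
#' @param max_mito_fraction Upper bound on the mitochondrial UMI fraction;
#'   cells at or above the bound are removed.
#' @param mito_prefix Prefix identifying mitochondrial genes ("mt-", the
#'   mouse convention); matched case-insensitively.
#' @param mito_genes Optional explicit mitochondrial gene list; overrides the
#'   prefix when given.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes = 200, max_mito_fraction = 0.15,
                      mito_prefix = "mt-", mito_genes = NULL) {
  stopifnot(min_genes >= 1, max_mito_fraction > 0, max_mito_fraction <= 1)
  structure(list(min_genes = as.integer(min_genes),
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix,
                 mito_genes = mito_genes),
            class = "qc_params")
}

mito_gene_ids <- function(gene_ids, params) {
  if (!is.null(params$mito_genes)) {
    return(intersect(params$mito_genes, gene_ids))
  }
  gene_ids[startsWith(tolower(gene_ids), tolower(params$mito_prefix))]
}

#' Filter cells on detected genes and mitochondrial content
#'
#' Retains cells with at least `min_genes` detected genes (count > 0) and a
#' mitochondrial UMI fraction strictly below `max_mito_fraction`. An empty
#' mitochondrial gene set gives every cell fraction 0.
#'
#' @param counts Genes x cells count matrix.
#' @param params A [qc_params()] object.
#' @return A list with `counts` (the retained columns) and `qc`, a per-cell
#'   table with genes detected, total UMIs, mito fraction, pass flag and the
#'   failure reason.
#' @export
filter_cells <- function(counts, params = qc_params()) {
  validate_counts(counts)
  mito <- mito_gene_ids(rownames(counts), params)
  n_genes <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito_umi <- if (length(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  mito_frac <- ifelse(total > 0, mito_umi / total, 0)
  pass_genes <- n_genes >= params$min_genes
  pass_mito <- mito_frac < params$max_mito_fraction
  pass <- pass_genes & pass_mito
  reason <- rep("", ncol(counts))
  reason[!pass_genes] <- "too_few_genes"
  reason[!pass_mito] <- ifelse(nzchar(reason[!pass_mito]),
                               "too_few_genes;high_mito", "high_mito")
  qc <- data.frame(cell_id = colnames(counts),
                   n_genes = as.integer(n_genes),
                   total_umi = as.numeric(total),
                   mito_fraction = as.numeric(mito_frac),
                   pass = pass,
                   reason = reason,
                   row.names = NULL)
  if (!any(pass)) stop("empty after QC: no cell passed the filters")
  list(counts = counts[, pass, drop = FALSE], qc = qc)
}

#' Log-normalize a count matrix
#'
#' Per cell, counts are divided by the cell's total UMI count, multiplied by
#' `scale_factor` and transformed with the natural log of (1 + x). The
#' sparsity pattern is preserved: zero counts map to exactly 0.
#'
#' @param counts Genes x cells count matrix; every cell must have total > 0.
#' @param scale_factor Target per-cell total on the linear scale.
#' @return A `dgCMatrix` of log-normalized values with attribute
#'   `scale_factor`.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  validate_counts(counts)
  stopifnot(scale_factor > 0)
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    stop("cells with zero total UMIs present; run filter_cells() first")
  }
  m <- methods::as(counts, "CsparseMatrix")
  # scale each column, then log1p on the stored non-zeros only
  cell_of_entry <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * scale_factor / total[cell_of_entry])
  attr(m, "scale_factor") <- scale_factor
  m
}
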
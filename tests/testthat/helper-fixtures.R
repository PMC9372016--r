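# Small in-code fixtures shared across tests.

# counts matrix with named genes/cells from a dense matrix
make_counts <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# random sparse count matrix
random_counts <- function(n_genes, n_cells, lambda = 0.5, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  make_counts(m)
}

# two-group annotation for a plain expression matrix
two_group_annotation <- function(cells, n1,
                                 conditions = c("control", "perturbed"),
                                 cell_type = "typeA") {
  data.frame(cell_id = cells,
             sample_id = "s1", tissue = "t", timepoint = "tp",
             condition = rep(conditions, c(n1, length(cells) - n1)),
             batch = "b1", cell_type = cell_type,
             stringsAsFactors = FALSE)
}

# log-normalized gaussian expression matrix (nonnegative) for direct tests
random_expr <- function(n_genes, n_cells, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(stats::rnorm(n_genes * n_cells)), n_genes, n_cells)
  make_counts(m)
}
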
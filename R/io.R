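#' Read a sparse UMI count matrix from a MatrixMarket triplet
#'
#' Reads the 10x-style triplet of a MatrixMarket `.mtx` file plus a features
#' file (one gene id per row) and a barcodes file (one cell id per row).
#' Genes are rows, cells are columns; file order is preserved. MatrixMarket
#' coordinates are 1-based per the standard.
#'
#' @param mtx_path Path to the MatrixMarket file.
#' @param features_path Path to the features TSV (first column = gene ids).
#' @param barcodes_path Path to the barcodes TSV (first column = cell ids).
#' @return A `dgCMatrix` of non-negative integer counts with gene ids as
#'   rownames and cell ids as colnames.
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- Matrix::readMM(mtx_path)
  feats <- utils::read.table(features_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "")[[1]]
  bcs <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "")[[1]]
  if (length(feats) != nrow(m)) {
    stop("format error: ", features_path, " has ", length(feats),
         " rows but ", mtx_path, " declares ", nrow(m), " rows")
  }
  if (length(bcs) != ncol(m)) {
    stop("format error: ", barcodes_path, " has ", length(bcs),
         " rows but ", mtx_path, " declares ", ncol(m), " columns")
  }
  m <- methods::as(m, "CsparseMatrix")
  if (any(m@x < 0)) stop("format error: negative entries in ", mtx_path)
  if (any(m@x != round(m@x))) {
    stop("format error: non-integer entries in ", mtx_path)
  }
  dimnames(m) <- list(feats, bcs)
  validate_counts(m)
  m
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param dir Output directory (created if absent). Writes `matrix.mtx`,
#'   `features.tsv` and `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir) {
  validate_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense genes-by-cells count table
#'
#' For toy data: TSV with gene ids in the first column and cell ids in the
#' header.
#'
#' @param path TSV path.
#' @return A sparse `dgCMatrix` of counts.
#' @export
read_dense_counts <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, quote = "")
  m <- as.matrix(tab)
  if (any(m < 0)) stop("format error: negative entries in ", path)
  if (any(m != round(m))) stop("format error: non-integer entries in ", path)
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  validate_counts(m)
  m
}

#' Write a dense genes-by-cells count table
#' @param counts Genes x cells count matrix.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_dense_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts),
                   as.matrix(counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell annotation table
#'
#' Requires columns `cell_id`, `sample_id`, `condition`, `cell_type`;
#' `tissue`, `timepoint` and `batch` are optional and default to a single
#' level. `condition` must be drawn from control/perturbed/treated.
#'
#' @param path TSV path.
#' @param counts Optional count matrix; if given, every cell id in the matrix
#'   must be annotated exactly once.
#' @return A data.frame keyed by `cell_id`.
#' @export
read_cell_annotation <- function(path, counts = NULL) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  required <- c("cell_id", "sample_id", "condition", "cell_type")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    stop("annotation is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  for (col in c("tissue", "timepoint", "batch")) {
    if (is.null(ann[[col]])) ann[[col]] <- "all"
  }
  validate_annotation(ann, counts)
  ann
}

validate_annotation <- function(annotation, counts = NULL) {
  if (anyDuplicated(annotation$cell_id)) {
    stop("duplicated cell_id in annotation")
  }
  bad <- setdiff(unique(annotation$condition),
                 c("control", "perturbed", "treated"))
  if (length(bad)) {
    stop("condition must be one of control/perturbed/treated; found: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(counts)) {
    unannotated <- setdiff(colnames(counts), annotation$cell_id)
    if (length(unannotated)) {
      stop(length(unannotated), " cells in the matrix have no annotation row",
           " (first: ", unannotated[1], ")")
    }
  }
  invisible(annotation)
}

#' Write a per-cell annotation table
#' @param annotation Annotation data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Read a two-column ligand-receptor pair table
#'
#' @param path TSV with columns `ligand` and `receptor` (header required).
#' @return data.frame with columns ligand, receptor.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("ligand", "receptor") %in% names(tab))) {
    stop("ligand-receptor table needs columns 'ligand' and 'receptor'")
  }
  tab[, c("ligand", "receptor")]
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene ids (rownames) and cell ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) stop("gene ids are not unique")
  if (anyDuplicated(colnames(counts))) stop("cell ids are not unique")
  invisible(counts)
}
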
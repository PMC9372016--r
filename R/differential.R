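#' Parameters for Wilcoxon differential expression
#'
#' @param min_expressed_fraction A gene must be expressed (value > 0) in at
#'   least this fraction of cells in one of the two groups to be tested.
#' @param min_abs_log_fc Minimum absolute natural-log fold change between
#'   group means (on the de-logged scale) to be tested.
#' @param alpha_adjusted Significance threshold on the Bonferroni-adjusted p.
#' @param log_fc_eps Pseudocount added to both group means in the fold
#'   change.
#' @return A list of class `deg_params`.
#' @export
deg_params <- function(min_expressed_fraction = 0.10, min_abs_log_fc = 0.25,
                       alpha_adjusted = 0.05, log_fc_eps = 1e-9) {
  stopifnot(min_expressed_fraction >= 0, min_expressed_fraction <= 1,
            min_abs_log_fc >= 0, alpha_adjusted > 0, alpha_adjusted < 1)
  structure(list(min_expressed_fraction = min_expressed_fraction,
                 min_abs_log_fc = min_abs_log_fc,
                 alpha_adjusted = alpha_adjusted,
                 log_fc_eps = log_fc_eps),
            class = "deg_params")
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Pre-filters genes to those expressed in at least
#' `min_expressed_fraction` of cells in one of the groups and with at least
#' `min_abs_log_fc` absolute log fold change between group means, then tests
#' each remaining gene with a two-sided Wilcoxon rank-sum test (exact
#' enumeration when both groups have at most 25 cells and the gene has no
#' ties; otherwise the normal approximation with tie and continuity
#' correction). Bonferroni correction is over the genes actually tested.
#'
#' The fold change is `ln((mean(expm1(x1)) + eps) / (mean(expm1(x2)) + eps))`
#' computed on the de-logged normalized values.
#'
#' @param expr Genes x cells log-normalized matrix.
#' @param cells_group1,cells_group2 Disjoint cell id (or index) vectors.
#' @param params A [deg_params()].
#' @return data.frame with columns gene, log_fc, pct_group1, pct_group2,
#'   p_raw, p_adjusted, direction — one row per gene passing the pre-filters.
#' @export
wilcoxon_de <- function(expr, cells_group1, cells_group2,
                        params = deg_params()) {
  if (length(cells_group1) == 0 || length(cells_group2) == 0) {
    stop("both groups must be nonempty")
  }
  if (length(intersect(cells_group1, cells_group2))) {
    stop("cell groups overlap")
  }
  x1 <- as.matrix(expr[, cells_group1, drop = FALSE])
  x2 <- as.matrix(expr[, cells_group2, drop = FALSE])
  pct1 <- rowMeans(x1 > 0)
  pct2 <- rowMeans(x2 > 0)
  m1 <- rowMeans(expm1(x1))
  m2 <- rowMeans(expm1(x2))
  log_fc <- log((m1 + params$log_fc_eps) / (m2 + params$log_fc_eps))
  keep <- (pmax(pct1, pct2) >= params$min_expressed_fraction) &
    (abs(log_fc) >= params$min_abs_log_fc)
  genes <- rownames(expr)[keep]
  if (!length(genes)) {
    return(data.frame(gene = character(0), log_fc = numeric(0),
                      pct_group1 = numeric(0), pct_group2 = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      direction = numeric(0), stringsAsFactors = FALSE))
  }
  p <- rank_sum_test(cbind(x1[keep, , drop = FALSE],
                           x2[keep, , drop = FALSE]),
                     n1 = ncol(x1))
  out <- data.frame(gene = genes, log_fc = log_fc[keep],
                    pct_group1 = pct1[keep], pct_group2 = pct2[keep],
                    p_raw = p,
                    p_adjusted = pmin(1, p * length(genes)),
                    direction = sign(log_fc[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p_raw, out$gene), , drop = FALSE]
}

# Row-wise two-sided Wilcoxon rank-sum p-values for a genes x cells matrix
# whose first n1 columns are group 1. Exact null enumeration (pwilcox) when
# both n <= 25 and a row has no ties; normal approximation with tie and
# continuity correction otherwise (matching stats::wilcox.test conventions).
rank_sum_test <- function(x, n1) {
  n <- ncol(x)
  n2 <- n - n1
  r <- matrixStats::rowRanks(x, ties.method = "average")
  u <- rowSums(r[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
  ties_term <- vapply(seq_len(nrow(x)), function(i) {
    len <- rle(sort.int(x[i, ], method = "radix"))$lengths
    sum(len^3) - n
  }, numeric(1))
  has_ties <- ties_term > 0
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - ties_term / (n * (n - 1))))
  p <- numeric(nrow(x))
  exact_ok <- (n1 <= 25 && n2 <= 25)
  for (i in seq_len(nrow(x))) {
    if (exact_ok && !has_ties[i]) {
      p[i] <- if (u[i] > mu) {
        min(1, 2 * stats::pwilcox(u[i] - 1, n1, n2, lower.tail = FALSE))
      } else {
        min(1, 2 * stats::pwilcox(u[i], n1, n2))
      }
    } else if (sigma[i] == 0) {
      p[i] <- 1
    } else {
      zc <- u[i] - mu
      zc <- zc - sign(zc) * 0.5   # continuity correction
      p[i] <- min(1, 2 * stats::pnorm(-abs(zc / sigma[i])))
    }
  }
  p
}

#' Conserved cluster markers across strata
#'
#' For each timepoint-by-condition stratum containing the cluster, runs
#' [wilcoxon_de()] of the cluster's cells against all other cells (same
#' pre-filters); genes passing the filters in every usable stratum get a
#' Tippett minimum-p meta p-value across strata, Bonferroni-corrected over
#' the genes meta-tested. Only genes with a consistent fold-change direction
#' in all strata and adjusted meta p below `alpha` are emitted.
#'
#' @param expr Genes x cells log-normalized matrix.
#' @param annotation Cell annotation data.frame.
#' @param cluster Cell type whose markers are sought.
#' @param params A [deg_params()].
#' @param strata_cols Annotation columns defining the strata.
#' @param min_cells Minimum cluster and non-cluster cells per usable stratum.
#' @return data.frame: gene, mean log_fc across strata, meta_p, p_adjusted,
#'   n_strata.
#' @export
conserved_markers <- function(expr, annotation, cluster,
                              params = deg_params(),
                              strata_cols = c("timepoint", "condition"),
                              min_cells = 10) {
  strat <- interaction(annotation[, strata_cols, drop = FALSE], drop = TRUE)
  tabs <- list()
  for (s in levels(strat)) {
    ann_s <- annotation[strat == s, , drop = FALSE]
    in_cl <- ann_s$cell_id[ann_s$cell_type == cluster]
    out_cl <- ann_s$cell_id[ann_s$cell_type != cluster]
    if (length(in_cl) < min_cells || length(out_cl) < min_cells) {
      warning("stratum ", s, " dropped: cluster absent or too few cells")
      next
    }
    tabs[[s]] <- wilcoxon_de(expr[, c(in_cl, out_cl), drop = FALSE],
                             in_cl, out_cl, params)
  }
  if (length(tabs) < 2) {
    stop("conserved_markers needs at least 2 usable strata, found ",
         length(tabs))
  }
  common <- Reduce(intersect, lapply(tabs, `[[`, "gene"))
  if (!length(common)) {
    return(data.frame(gene = character(0), log_fc = numeric(0),
                      meta_p = numeric(0), p_adjusted = numeric(0),
                      n_strata = integer(0)))
  }
  k <- length(tabs)
  per_gene <- vapply(common, function(g) {
    rows <- lapply(tabs, function(t) t[t$gene == g, , drop = FALSE])
    ps <- vapply(rows, `[[`, numeric(1), "p_raw")
    dirs <- vapply(rows, `[[`, numeric(1), "direction")
    c(meta_p = tippett_meta_p(ps, k),
      log_fc = mean(vapply(rows, `[[`, numeric(1), "log_fc")),
      consistent = as.numeric(length(unique(dirs)) == 1))
  }, numeric(3))
  out <- data.frame(gene = common,
                    log_fc = per_gene["log_fc", ],
                    meta_p = per_gene["meta_p", ],
                    consistent = per_gene["consistent", ] == 1,
                    n_strata = k, stringsAsFactors = FALSE)
  out$p_adjusted <- pmin(1, out$meta_p * length(common))
  out <- out[out$consistent & out$p_adjusted < params$alpha_adjusted, ,
             drop = FALSE]
  out$consistent <- NULL
  rownames(out) <- NULL
  out[order(out$p_adjusted, out$gene), , drop = FALSE]
}

#' Genes reversed by a treatment
#'
#' Given DE tables for perturbed-vs-control and treated-vs-perturbed in the
#' same cell type, returns the genes significant (adjusted p < alpha) in
#' both with opposite fold-change direction — the signature of an effect
#' reversed by the treatment.
#'
#' @param deg_perturbed_vs_control,deg_treated_vs_perturbed
#'   [wilcoxon_de()]-style tables.
#' @param alpha Threshold on the adjusted p-values.
#' @return data.frame: gene, both log fold changes and adjusted p-values.
#' @export
reversed_genes <- function(deg_perturbed_vs_control,
                           deg_treated_vs_perturbed, alpha = 0.05) {
  a <- deg_perturbed_vs_control
  b <- deg_treated_vs_perturbed
  m <- merge(a[a$p_adjusted < alpha, c("gene", "log_fc", "p_adjusted")],
             b[b$p_adjusted < alpha, c("gene", "log_fc", "p_adjusted")],
             by = "gene", suffixes = c("_perturbed", "_treated"))
  m <- m[sign(m$log_fc_perturbed) * sign(m$log_fc_treated) < 0, ,
         drop = FALSE]
  rownames(m) <- NULL
  m[order(m$gene), , drop = FALSE]
}

#' Fisher's exact pathway enrichment
#'
#' One-sided (greater) Fisher's exact test of query-gene overlap with each
#' gene set, against the expressed-gene universe, with Benjamini-Hochberg
#' correction across the sets tested. Query and sets are intersected with
#' the universe first.
#'
#' @param query_genes Character vector (e.g. the significant DEGs).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector of background genes.
#' @return data.frame: gene_set, overlap, set_size, query_size,
#'   universe_size, p_raw, fdr; sorted by p_raw.
#' @export
fisher_enrichment <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  query <- intersect(unique(query_genes), universe)
  sets <- lapply(gene_sets, intersect, universe)
  res <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- length(intersect(query, s))
    tab <- matrix(c(ov,
                    length(query) - ov,
                    length(s) - ov,
                    length(universe) - length(query) - length(s) + ov),
                  nrow = 2)
    data.frame(gene_set = nm, overlap = ov, set_size = length(s),
               query_size = length(query), universe_size = length(universe),
               p_raw = stats::fisher.test(tab, alternative = "greater")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_raw, method = "BH")
  rownames(out) <- NULL
  out[order(out$p_raw, out$gene_set), , drop = FALSE]
}
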
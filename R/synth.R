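#' Configuration for the synthetic droplet scRNA-seq generator
#'
#' Defines a two-condition (control vs perturbed) multi-cell-type experiment
#' with negative-binomial UMI counts, per-cell-type perturbation magnitudes,
#' mitochondrial genes, batches and optionally planted ligand-receptor
#' co-expression. The per-type "true effect size" is
#' `fraction_de * abs(effect_log_fc)`.
#'
#' @param n_cell_types Number of cell types.
#' @param cells_per_type_per_condition Cells per type per condition (scalar
#'   or per-type vector).
#' @param n_genes Total genes (including mitochondrial ones).
#' @param gene_mean_meanlog,gene_mean_sdlog Log-normal parameters of the
#'   per-gene baseline mean (UMIs per cell).
#' @param nb_dispersion Negative-binomial size parameter (shared).
#' @param fraction_de Per-type fraction of genes differentially expressed in
#'   the perturbed condition (scalar or per-type vector).
#' @param effect_log_fc Per-type natural-log fold change applied to DE genes
#'   (scalar or per-type vector).
#' @param de_up_fraction Fraction of DE genes shifted up (rest down).
#' @param mito_fraction_target Expected mitochondrial UMI fraction.
#' @param n_mito_genes Number of mitochondrial genes (ids prefixed "mt-").
#' @param n_batches Number of batches (cells assigned evenly at random).
#' @param batch_effect_log_fc Natural-log shift applied, in batches after the
#'   first, to a random `batch_gene_fraction` subset of genes.
#' @param batch_gene_fraction Fraction of genes carrying the batch effect.
#' @param libsize_sdlog Log-normal sd of the per-cell library-size factor.
#' @param planted_lr Optional data.frame with columns ligand, receptor,
#'   type_a, type_b, boost_log_fc: the ligand's mean is boosted in type_a
#'   cells and the receptor's in type_b cells.
#' @param tissue,timepoint Labels stamped on every cell.
#' @param seed Mandatory integer seed; identical config + seed gives
#'   bit-identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cell_types = 4,
                         cells_per_type_per_condition = 150,
                         n_genes = 2000,
                         gene_mean_meanlog = -1,
                         gene_mean_sdlog = 1,
                         nb_dispersion = 2,
                         fraction_de = c(0, 0.15, 0.30, 0.40),
                         effect_log_fc = 2,
                         de_up_fraction = 0.5,
                         mito_fraction_target = 0.05,
                         n_mito_genes = 13,
                         n_batches = 2,
                         batch_effect_log_fc = 0,
                         batch_gene_fraction = 0.10,
                         libsize_sdlog = 0.3,
                         planted_lr = NULL,
                         tissue = "synthetic",
                         timepoint = "t0",
                         seed = 1L) {
  stopifnot(n_cell_types >= 1, n_genes > n_mito_genes, nb_dispersion > 0,
            de_up_fraction >= 0, de_up_fraction <= 1,
            mito_fraction_target >= 0, mito_fraction_target < 1,
            n_batches >= 1, batch_gene_fraction >= 0, batch_gene_fraction <= 1,
            !is.null(seed))
  rec <- function(x) rep_len(x, n_cell_types)
  fraction_de <- rec(fraction_de)
  effect_log_fc <- rec(effect_log_fc)
  if (any(fraction_de < 0 | fraction_de > 1)) {
    stop("fraction_de must lie in [0, 1]")
  }
  structure(list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type_per_condition = rec(as.integer(cells_per_type_per_condition)),
    n_genes = as.integer(n_genes),
    gene_mean_meanlog = gene_mean_meanlog,
    gene_mean_sdlog = gene_mean_sdlog,
    nb_dispersion = nb_dispersion,
    fraction_de = fraction_de,
    effect_log_fc = effect_log_fc,
    de_up_fraction = de_up_fraction,
    mito_fraction_target = mito_fraction_target,
    n_mito_genes = as.integer(n_mito_genes),
    n_batches = as.integer(n_batches),
    batch_effect_log_fc = batch_effect_log_fc,
    batch_gene_fraction = batch_gene_fraction,
    libsize_sdlog = libsize_sdlog,
    planted_lr = planted_lr,
    tissue = tissue,
    timepoint = timepoint,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a synthetic dataset with ground truth
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `mu_g * libsize * exp(sum of applicable log-FC offsets)` where the offsets
#' come from the per-type condition effect, the batch effect and any planted
#' ligand-receptor boost. Mitochondrial gene means are tuned so the expected
#' mitochondrial fraction equals `mito_fraction_target`.
#'
#' @param config A [synth_config()].
#' @return A list with `counts` (sparse genes x cells), `annotation`
#'   (data.frame: cell_id, sample_id, tissue, timepoint, condition, batch,
#'   cell_type) and `truth` (per-type effect sizes and DE gene lists, planted
#'   LR pairs).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  G <- config$n_genes
  n_mito <- config$n_mito_genes
  gene_ids <- c(sprintf("gene%04d", seq_len(G - n_mito)),
                if (n_mito > 0) sprintf("mt-gene%02d", seq_len(n_mito)))
  mito_idx <- if (n_mito > 0) (G - n_mito + 1):G else integer(0)

  mu <- stats::rlnorm(G, config$gene_mean_meanlog, config$gene_mean_sdlog)
  if (n_mito > 0 && config$mito_fraction_target > 0) {
    non_mito_sum <- sum(mu[-mito_idx])
    target_mito_sum <- config$mito_fraction_target /
      (1 - config$mito_fraction_target) * non_mito_sum
    mu[mito_idx] <- target_mito_sum / n_mito
  }

  types <- sprintf("type%d", seq_len(config$n_cell_types))
  conditions <- c("control", "perturbed")

  # planted condition DE genes per type (never mitochondrial)
  candidate <- setdiff(seq_len(G), mito_idx)
  de_sets <- vector("list", config$n_cell_types)
  names(de_sets) <- types
  de_dirs <- vector("list", config$n_cell_types)
  for (t in seq_len(config$n_cell_types)) {
    n_de <- round(config$fraction_de[t] * G)
    idx <- if (n_de > 0) sort(sample(candidate, min(n_de, length(candidate)))) else integer(0)
    n_up <- round(config$de_up_fraction * length(idx))
    dir <- rep(-1, length(idx))
    if (n_up > 0) dir[seq_len(n_up)] <- 1
    de_sets[[t]] <- idx
    de_dirs[[t]] <- dir
  }

  batch_gene_idx <- sort(sample(seq_len(G),
                                round(config$batch_gene_fraction * G)))

  if (!is.null(config$planted_lr)) {
    lr <- config$planted_lr
    bad <- setdiff(unique(c(lr$ligand, lr$receptor)), gene_ids)
    if (length(bad)) {
      stop("config error: planted LR gene(s) not in the gene universe: ",
           paste(bad, collapse = ", "))
    }
    bad_t <- setdiff(unique(c(lr$type_a, lr$type_b)), types)
    if (length(bad_t)) {
      stop("config error: planted LR cell type(s) unknown: ",
           paste(bad_t, collapse = ", "))
    }
  }

  cells_per <- config$cells_per_type_per_condition
  n_cells <- sum(cells_per) * 2L
  counts <- matrix(0L, nrow = G, ncol = n_cells)
  ann <- data.frame(cell_id = character(n_cells), sample_id = character(n_cells),
                    tissue = config$tissue, timepoint = config$timepoint,
                    condition = character(n_cells), batch = character(n_cells),
                    cell_type = character(n_cells), stringsAsFactors = FALSE)
  col <- 0L
  for (t in seq_len(config$n_cell_types)) {
    for (cond in conditions) {
      nct <- cells_per[t]
      log_mu <- log(mu)
      if (cond == "perturbed" && length(de_sets[[t]])) {
        log_mu[de_sets[[t]]] <- log_mu[de_sets[[t]]] +
          de_dirs[[t]] * config$effect_log_fc[t]
      }
      if (!is.null(config$planted_lr)) {
        lr <- config$planted_lr
        for (i in seq_len(nrow(lr))) {
          if (lr$type_a[i] == types[t]) {
            gi <- match(lr$ligand[i], gene_ids)
            log_mu[gi] <- log_mu[gi] + lr$boost_log_fc[i]
          }
          if (lr$type_b[i] == types[t]) {
            gi <- match(lr$receptor[i], gene_ids)
            log_mu[gi] <- log_mu[gi] + lr$boost_log_fc[i]
          }
        }
      }
      batches <- sample(rep_len(seq_len(config$n_batches), nct))
      lib <- stats::rlnorm(nct, -config$libsize_sdlog^2 / 2,
                           config$libsize_sdlog)
      for (j in seq_len(nct)) {
        col <- col + 1L
        lm <- log_mu
        if (batches[j] > 1 && config$batch_effect_log_fc != 0) {
          lm[batch_gene_idx] <- lm[batch_gene_idx] + config$batch_effect_log_fc
        }
        counts[, col] <- stats::rnbinom(G, size = config$nb_dispersion,
                                        mu = exp(lm) * lib[j])
        ann$cell_id[col] <- sprintf("cell%05d", col)
        ann$condition[col] <- cond
        ann$batch[col] <- sprintf("batch%d", batches[j])
        ann$sample_id[col] <- sprintf("%s_batch%d", cond, batches[j])
        ann$cell_type[col] <- types[t]
      }
    }
  }
  dimnames(counts) <- list(gene_ids, ann$cell_id)
  truth <- list(
    cell_types = types,
    effect_size = stats::setNames(
      config$fraction_de * abs(config$effect_log_fc), types),
    de_genes = lapply(de_sets, function(i) gene_ids[i]),
    de_direction = de_dirs,
    batch_genes = gene_ids[batch_gene_idx],
    planted_lr = config$planted_lr,
    mito_genes = gene_ids[mito_idx]
  )
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       annotation = ann,
       truth = truth)
}

#' Generate an LR-focused synthetic dataset
#'
#' Convenience wrapper over [generate_dataset()] that plants ligand-receptor
#' co-expression between chosen cluster pairs; with `boost_log_fc = 0` all
#' pairs are exchangeable across clusters (a null dataset).
#'
#' @param config A [synth_config()] with at least 2 cell types; if
#'   `planted_lr` is NULL a single default pair
#'   (gene0001 -> gene0002, type1 -> type2, boost 2) is planted.
#' @return As [generate_dataset()].
#' @export
planted_lr_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_cell_types < 2) stop("planted_lr_dataset needs >= 2 cell types")
  if (is.null(config$planted_lr)) {
    config$planted_lr <- data.frame(
      ligand = "gene0001", receptor = "gene0002",
      type_a = "type1", type_b = "type2",
      boost_log_fc = 2, stringsAsFactors = FALSE)
  }
  generate_dataset(config)
}
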
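#' Assemble an end-to-end analysis configuration
#'
#' Either `synth` (a [synth_config()]) or the `counts`/`annotation` paths
#' must be supplied. Stages can be disabled by name; dependencies (qc before
#' everything, normalization before the metrics) always run.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives a stable sub-seed
#'   from it.
#' @param synth Optional [synth_config()] used to generate the input data.
#' @param counts_dir Optional MTX-triplet directory (used when `synth` is
#'   NULL).
#' @param annotation_path Optional annotation TSV (with `counts_dir`).
#' @param lr_pairs_path Optional ligand-receptor pair TSV; enables the
#'   coordination stage.
#' @param gmt_path Optional GMT file; enables pathway enrichment of the DEGs.
#' @param qc A [qc_params()].
#' @param shift A [shift_params()].
#' @param deg A [deg_params()].
#' @param stages Character vector of stages to run, among
#'   `c("qc", "sensitivity", "de", "lr", "batchqc")`.
#' @param lr_n_permutations,lr_alpha Coordination-stage parameters.
#' @param batch_col,batch_n_runs Batch-QC parameters.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(out_dir, seed,
                            synth = NULL, counts_dir = NULL,
                            annotation_path = NULL,
                            lr_pairs_path = NULL, gmt_path = NULL,
                            qc = qc_params(), shift = shift_params(),
                            deg = deg_params(),
                            stages = c("qc", "sensitivity", "de", "lr",
                                       "batchqc"),
                            lr_n_permutations = 1000, lr_alpha = 0.05,
                            batch_col = "batch", batch_n_runs = 100) {
  if (is.null(synth) && (is.null(counts_dir) || is.null(annotation_path))) {
    stop("supply either a synth_config or counts_dir + annotation_path")
  }
  if (is.null(seed)) stop("seed is mandatory")
  for (p in c(counts_dir, annotation_path, lr_pairs_path, gmt_path)) {
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 counts_dir = counts_dir, annotation_path = annotation_path,
                 lr_pairs_path = lr_pairs_path, gmt_path = gmt_path,
                 qc = qc, shift = shift, deg = deg, stages = stages,
                 lr_n_permutations = lr_n_permutations, lr_alpha = lr_alpha,
                 batch_col = batch_col, batch_n_runs = batch_n_runs),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML mirrors the arguments of [analysis_config()]; nested blocks
#' `synth`, `qc`, `shift` and `deg` are passed to the corresponding
#' constructors.
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$synth)) args$synth <- do.call(synth_config, y$synth)
  if (!is.null(y$qc)) args$qc <- do.call(qc_params, y$qc)
  if (!is.null(y$shift)) args$shift <- do.call(shift_params, y$shift)
  if (!is.null(y$deg)) args$deg <- do.call(deg_params, y$deg)
  do.call(analysis_config, args)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order — synthesis (optional),
#' QC + normalization, the three-metric sensitivity report, differential
#' expression (with treatment-reversal when a `treated` condition is
#' present, and pathway enrichment when a GMT is supplied), the
#' ligand-receptor coordination test (when a pair table is supplied) and
#' batch-mixing QC — writing per-stage TSV outputs and a JSON run manifest.
#' Identical configuration and seed give identical outputs.
#'
#' @param config An [analysis_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("scshift")),
    seed = config$seed,
    parameter_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    stages = list())
  outfile <- function(name) file.path(config$out_dir, name)
  stage_done <- function(name, outputs) {
    manifest$stages[[name]] <<- list(status = "completed", outputs = outputs)
  }
  stage_skipped <- function(name, why) {
    manifest$stages[[name]] <<- list(status = "skipped", reason = why)
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  counts <- NULL
  annotation <- NULL
  expr <- NULL

  # --- input data ---
  if (!is.null(config$synth)) {
    run_stage("synth", function() {
      cfg <- config$synth
      cfg$seed <- sub_seed(config$seed, "synth")
      ds <- generate_dataset(cfg)
      write_count_matrix(ds$counts, outfile("counts"))
      write_cell_annotation(ds$annotation, outfile("annotation.tsv"))
      jsonlite::write_json(ds$truth, outfile("truth.json"),
                           auto_unbox = TRUE, null = "null")
      stage_done("synth", c("counts", "annotation.tsv", "truth.json"))
      counts <<- ds$counts
      annotation <<- ds$annotation
    })
  } else {
    stage_skipped("synth", "external input supplied")
    counts <- read_count_matrix(file.path(config$counts_dir, "matrix.mtx"),
                                file.path(config$counts_dir, "features.tsv"),
                                file.path(config$counts_dir, "barcodes.tsv"))
    annotation <- read_cell_annotation(config$annotation_path, counts)
  }

  # --- qc + normalization (always run) ---
  run_stage("qc", function() {
    f <- filter_cells(counts, config$qc)
    utils::write.table(f$qc, outfile("qc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts <<- f$counts
    annotation <<- annotation[annotation$cell_id %in% colnames(f$counts), ,
                              drop = FALSE]
    expr <<- normalize_counts(f$counts)
    stage_done("qc", "qc.tsv")
  })

  shift <- config$shift
  shift$seed <- sub_seed(config$seed, "shift")

  if ("sensitivity" %in% config$stages) {
    run_stage("sensitivity", function() {
      rep <- sensitivity_report(expr, annotation, shift, config$deg)
      rep$avg_rank_2dp <- round(rep$avg_rank, 2)
      utils::write.table(rep, outfile("sensitivity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      stage_done("sensitivity", "sensitivity.tsv")
    })
  } else stage_skipped("sensitivity", "disabled")

  if ("de" %in% config$stages) {
    run_stage("de", function() {
      degs <- list(); reversed <- list()
      for (ct in sort(unique(annotation$cell_type))) {
        grp <- group_cells(annotation, ct, c("control", "perturbed"))
        if (min(lengths(grp)) < config$shift$min_cells_per_group) next
        d <- wilcoxon_de(expr, grp$perturbed, grp$control, config$deg)
        if (nrow(d)) degs[[ct]] <- cbind(cell_type = ct, d)
        tr <- annotation$cell_id[annotation$cell_type == ct &
                                   annotation$condition == "treated"]
        if (length(tr) >= config$shift$min_cells_per_group && nrow(d)) {
          d2 <- wilcoxon_de(expr, tr, grp$perturbed, config$deg)
          rv <- reversed_genes(d, d2, config$deg$alpha_adjusted)
          if (nrow(rv)) reversed[[ct]] <- cbind(cell_type = ct, rv)
        }
      }
      deg_tab <- if (length(degs)) do.call(rbind, degs) else
        data.frame(cell_type = character(0))
      utils::write.table(deg_tab, outfile("degs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- "degs.tsv"
      if (length(reversed)) {
        utils::write.table(do.call(rbind, reversed), outfile("reversed.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, "reversed.tsv")
      }
      if (!is.null(config$gmt_path) && nrow(deg_tab) > 0) {
        sets <- read_gmt(config$gmt_path)
        sig <- unique(deg_tab$gene[deg_tab$p_adjusted <
                                     config$deg$alpha_adjusted])
        enr <- fisher_enrichment(sig, sets, rownames(expr))
        utils::write.table(enr, outfile("enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, "enrichment.tsv")
      }
      stage_done("de", outputs)
    })
  } else stage_skipped("de", "disabled")

  if ("lr" %in% config$stages && !is.null(config$lr_pairs_path)) {
    run_stage("lr", function() {
      pairs <- read_lr_pairs(config$lr_pairs_path)
      res <- lr_interaction_test(expr, annotation, pairs,
                                 n_permutations = config$lr_n_permutations,
                                 alpha = config$lr_alpha,
                                 seed = sub_seed(config$seed, "lr"))
      utils::write.table(res$detail, outfile("lr_detail.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(res$matrix_symmetric, outfile("lr_matrix.tsv"),
                         sep = "\t", quote = FALSE)
      stage_done("lr", c("lr_detail.tsv", "lr_matrix.tsv"))
    })
  } else {
    stage_skipped("lr", if (!"lr" %in% config$stages) "disabled" else
      "no ligand-receptor pair table supplied")
  }

  if ("batchqc" %in% config$stages) {
    run_stage("batchqc", function() {
      bq <- batch_mixing_all(expr, annotation, batch_col = config$batch_col,
                             n_runs = config$batch_n_runs,
                             seed = sub_seed(config$seed, "batchqc"))
      utils::write.table(bq, outfile("batchqc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      stage_done("batchqc", "batchqc.tsv")
    })
  } else stage_skipped("batchqc", "disabled")

  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Published consensus-rank table
#'
#' The 18-row table of per-method ranks (Euclidean distance, SVM classifier,
#' subsampled DEG count) and the printed average rank for the top cell types
#' per tissue and timepoint, bundled for arithmetic cross-checks of
#' [consensus_rank()].
#'
#' @return data.frame: tissue, timepoint, cell_type, ed_rank, svm_rank,
#'   deg_rank, avg_rank.
#' @export
published_consensus_ranks <- function() {
  utils::read.table(system.file("extdata", "consensus_ranks_published.tsv",
                                package = "scshift"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
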
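#' Configuration for an analysis track
#'
#' Collects the inputs of [run_track()]. Exactly which fields are used
#' depends on the track; validation happens at run time against the
#' requested track.
#'
#' @param expression an `expr_matrix` (counts for the bulk tracks).
#' @param samples a [sample_table()].
#' @param gene_sets named list of [gene_set()] objects to score.
#' @param myeloid_set a [gene_set()] of myeloid marker genes (whole
#'   tissue track: used for balancing).
#' @param cells a [cell_matrix()] (pseudobulk track).
#' @param qc a [qc_rule()] (pseudobulk track).
#' @param clusters cell-type/cluster labels to keep for pseudobulk
#'   aggregation (default: all).
#' @param min_cells minimum cells per pseudobulk (default 10).
#' @param neuronal_exclusion gene ids removed from the target sets on
#'   the whole-tissue track.
#' @param apoe_gene gene id removed from target sets on the pseudobulk
#'   track (default "APOE"; set NULL to keep).
#' @param extra_datasets optional list of `expr_matrix` objects whose
#'   gene universes the sets are restricted to (cross-study
#'   comparability).
#' @param n_bins,seed balancing parameters (seed mandatory when the
#'   whole-tissue track is run).
#' @param dataset_label tag recorded on score tables.
#' @param variant t-test variant for group comparisons.
#' @param out_dir optional directory: when set, score tables,
#'   comparisons and a JSON run manifest are written there.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(expression = NULL, samples = NULL,
                       gene_sets = list(), myeloid_set = NULL,
                       cells = NULL, qc = NULL, clusters = NULL,
                       min_cells = 10L,
                       neuronal_exclusion = character(0),
                       apoe_gene = "APOE", extra_datasets = list(),
                       n_bins = 20L, seed = NULL,
                       dataset_label = "dataset1",
                       variant = "student", out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

center_on_controls <- function(counts, samples, dataset_label) {
  logm <- log_stabilize(counts)
  ctrl <- samples$sample_id[samples$diagnosis == "control"]
  ctrl <- intersect(ctrl, colnames(logm))
  if (length(ctrl) == 1L)
    message("dataset '", dataset_label,
            "': only one control sample; centering on it")
  control_center(logm, ctrl)
}

score_and_compare <- function(centered, samples, sets, config, log) {
  scores <- list(); comparisons <- list()
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (length(s$members) == 0L) {
      log$skipped_sets <- c(log$skipped_sets, nm)
      next
    }
    st <- de_score(centered, s, dataset_label = config$dataset_label)
    scores[[nm]] <- st
    log$n_genes_used[[nm]] <- attr(st, "n_genes_used")
    cmp <- compare_groups(st, samples, variant = config$variant)
    comparisons[[nm]] <- data.frame(
      gene_set = nm, delta = cmp$delta, p_value = cmp$p_value,
      n_A = cmp$group_sizes[1L], n_B = cmp$group_sizes[2L],
      n_genes_used = attr(st, "n_genes_used"), row.names = NULL)
  }
  list(scores = scores,
       comparisons = do.call(rbind, comparisons), log = log)
}

#' Run one of the three analysis tracks
#'
#' \describe{
#'   \item{sorted_cells}{log-stabilize, center on the dataset's
#'     controls, score every configured gene set (signed), compare
#'     diagnosis groups.}
#'   \item{whole_tissue_balanced}{score the myeloid marker set, build
#'     a seeded [myeloid_balance()] plan, drop discarded samples,
#'     remove the neuronal exclusion list from target sets, restrict
#'     sets to genes shared with any extra datasets, re-score on the
#'     balanced subset and compare.}
#'   \item{pseudobulk}{QC-filter cells, keep the designated clusters,
#'     aggregate per (sample, type), size-factor normalize,
#'     log-stabilize, center on the dataset's control pseudobulks,
#'     score with APOE removed, compare.}
#' }
#' All dropped-gene counts, set sizes, seeds and the balance plan are
#' returned in the result and written to a JSON manifest when
#' `out_dir` is set. Gene set scores are signed ([de_score()]); plain
#' sets give the unweighted score by construction.
#'
#' @param config a [run_config()].
#' @param track `"sorted_cells"`, `"whole_tissue_balanced"` or
#'   `"pseudobulk"`.
#' @return a list with `scores` (named list of score tables),
#'   `comparisons` (data.frame), `log`, and per-track extras
#'   (`balance` plan, `pseudobulk` matrix).
#' @export
run_track <- function(config, track = c("sorted_cells",
                                        "whole_tissue_balanced",
                                        "pseudobulk")) {
  track <- match.arg(track)
  stopifnot(inherits(config, "run_config"))
  log <- list(track = track, dataset = config$dataset_label,
              skipped_sets = character(0), n_genes_used = list())
  res <- switch(track,
    sorted_cells = {
      samples <- sample_table(config$samples)
      centered <- center_on_controls(config$expression, samples,
                                     config$dataset_label)
      sets <- restrict_sets(config$gene_sets, centered, config, log)
      score_and_compare(centered, samples, sets$sets, config,
                        sets$log)
    },
    whole_tissue_balanced = {
      if (is.null(config$seed))
        stop("balancing requires a seed in the config", call. = FALSE)
      if (is.null(config$myeloid_set))
        stop("whole-tissue track requires a myeloid marker set",
             call. = FALSE)
      samples <- sample_table(config$samples)
      centered <- center_on_controls(config$expression, samples,
                                     config$dataset_label)
      my_score <- gene_set_score(centered, config$myeloid_set,
                                 dataset_label = config$dataset_label)
      plan <- myeloid_balance(my_score, samples,
                              n_bins = config$n_bins,
                              seed = config$seed)
      log$n_kept <- length(plan$kept_sample_ids)
      log$n_discarded <- length(plan$discarded_sample_ids)
      kept <- plan$kept_sample_ids
      sub <- expression_matrix(
        unclass(centered)[, kept, drop = FALSE], "centered")
      samples_kept <- samples[samples$sample_id %in% kept, ]
      targets <- lapply(config$gene_sets, exclude_genes,
                        exclusion = config$neuronal_exclusion)
      sets <- restrict_sets(targets, sub, config, log)
      out <- score_and_compare(sub, samples_kept, sets$sets, config,
                               sets$log)
      out$balance <- plan
      out$myeloid_scores <- my_score
      out
    },
    pseudobulk = {
      cells <- config$cells
      if (!is.null(config$qc))
        cells <- qc_filter_cells(cells, config$qc)
      log$qc <- attr(cells, "qc_report")
      if (!is.null(config$clusters)) {
        keep <- cells$cell_type %in% config$clusters
        cells$counts <- cells$counts[, keep, drop = FALSE]
        cells$cell_sample <- cells$cell_sample[keep]
        cells$cell_type <- cells$cell_type[keep]
      }
      pb <- aggregate_pseudobulk(cells, min_cells = config$min_cells)
      log$n_pseudobulks <- ncol(pb$counts)
      norm <- pseudobulk_normalize(pb)
      samples <- sample_table(config$samples)
      diag_of <- stats::setNames(as.character(samples$diagnosis),
                                 samples$sample_id)
      pb_samples <- sample_table(data.frame(
        sample_id = colnames(norm),
        diagnosis = diag_of[pb$sample], stringsAsFactors = FALSE))
      centered <- center_on_controls(
        expression_matrix(unclass(norm), "normalizedCount"),
        pb_samples, config$dataset_label)
      targets <- config$gene_sets
      if (!is.null(config$apoe_gene))
        targets <- lapply(targets, exclude_genes,
                          exclusion = config$apoe_gene)
      sets <- restrict_sets(targets, centered, config, log)
      out <- score_and_compare(centered, pb_samples, sets$sets,
                               config, sets$log)
      out$pseudobulk <- pb
      out
    })
  res$log <- utils::modifyList(log, res$log)
  if (!is.null(config$out_dir)) write_run_outputs(res, config)
  res
}

restrict_sets <- function(sets, centered, config, log) {
  datasets <- c(list(centered), config$extra_datasets)
  restricted <- restrict_to_shared_genes(sets, datasets)
  log$set_sizes <- lapply(restricted, function(s) length(s$members))
  list(sets = restricted, log = log)
}

write_run_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$scores))
    utils::write.csv(as.data.frame(res$scores[[nm]]),
                     file.path(config$out_dir,
                               paste0("scores_", nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(res$comparisons))
    utils::write.csv(res$comparisons,
                     file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
  manifest <- res$log
  manifest$seed <- config$seed
  manifest$n_bins <- config$n_bins
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
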
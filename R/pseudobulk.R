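#' Single-cell QC rule
#'
#' A conjunction of per-cell criteria; a cell is kept iff it satisfies
#' every criterion that is set, with inclusive boundaries: total UMIs
#' >= `min_total_umi`, log10(total UMIs) >= `min_log10_umi`,
#' mitochondrial fraction <= `max_mito_fraction`.
#'
#' Presets reproduce the filters used for three published
#' single-cell/nucleus datasets this package's analyses drew on:
#' \describe{
#'   \item{masuda}{fresh-resection CD45+ scRNA-seq: discard cells with
#'     < 800 total transcripts or > 30\% mitochondrial transcripts.}
#'   \item{jakel}{post-mortem snRNA-seq: keep nuclei with at least 400
#'     total UMIs.}
#'   \item{hasselmann}{xenotransplanted-microglia scRNA-seq: keep cells
#'     with log10(total UMIs) >= 3.25 and at most 5\% mitochondrial
#'     transcripts.}
#' }
#'
#' @param min_total_umi,min_log10_umi,max_mito_fraction criteria
#'   (NULL = unset). At least one must be set.
#' @param preset `"masuda"`, `"jakel"` or `"hasselmann"`; overrides the
#'   individual criteria.
#' @return a list of class `"qc_rule"`.
#' @export
qc_rule <- function(min_total_umi = NULL, min_log10_umi = NULL,
                    max_mito_fraction = NULL, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("masuda", "jakel", "hasselmann"))
    return(switch(preset,
      masuda = qc_rule(min_total_umi = 800, max_mito_fraction = 0.30),
      jakel = qc_rule(min_total_umi = 400),
      hasselmann = qc_rule(min_log10_umi = 3.25,
                           max_mito_fraction = 0.05)))
  }
  if (is.null(min_total_umi) && is.null(min_log10_umi) &&
      is.null(max_mito_fraction))
    stop("a QC rule needs at least one criterion", call. = FALSE)
  if (!is.null(max_mito_fraction) &&
      (max_mito_fraction < 0 || max_mito_fraction > 1))
    stop("max_mito_fraction must be in [0, 1]", call. = FALSE)
  structure(list(min_total_umi = min_total_umi,
                 min_log10_umi = min_log10_umi,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_rule")
}

#' Apply a QC rule to cells
#'
#' @param cells a [cell_matrix()].
#' @param rule a [qc_rule()].
#' @return the filtered `cell_matrix`, with a `qc_report` attribute
#'   recording cells in/out per criterion.
#' @export
qc_filter_cells <- function(cells, rule) {
  stopifnot(inherits(rule, "qc_rule"))
  tot <- cell_totals(cells)
  keep <- rep(TRUE, length(tot))
  report <- list(n_in = length(tot))
  if (!is.null(rule$min_total_umi)) {
    ok <- tot >= rule$min_total_umi
    report$fail_min_total_umi <- sum(!ok)
    keep <- keep & ok
  }
  if (!is.null(rule$min_log10_umi)) {
    ok <- log10(pmax(tot, 1)) >= rule$min_log10_umi & tot > 0
    report$fail_min_log10_umi <- sum(!ok)
    keep <- keep & ok
  }
  if (!is.null(rule$max_mito_fraction)) {
    if (length(cells$mito_genes) == 0L)
      stop("mito criterion set but no mito genes defined",
           call. = FALSE)
    ok <- mito_fraction(cells) <= rule$max_mito_fraction
    report$fail_max_mito_fraction <- sum(!ok)
    keep <- keep & ok
  }
  report$n_kept <- sum(keep)
  out <- cells
  out$counts <- cells$counts[, keep, drop = FALSE]
  out$cell_sample <- cells$cell_sample[keep]
  out$cell_type <- cells$cell_type[keep]
  attr(out, "qc_report") <- report
  out
}

#' Aggregate cells into per-(sample, cell type) pseudobulk profiles
#'
#' For each (sample s, cell type c) pair with at least `min_cells`
#' cells, sums the raw UMIs of each gene over those cells:
#' B[i, (s,c)] = sum over cells j with (s_j, c_j) = (s, c) of n[i, j].
#' Groups with fewer than `min_cells` cells produce no column.
#'
#' @param cells a [cell_matrix()] (QC-filtered, restricted to the
#'   clusters of interest by the caller).
#' @param min_cells minimum cells per (sample, type) group (default
#'   10).
#' @return a list of class `"pseudobulk_matrix"`: `counts` (genes x
#'   pseudobulks, column names `sample|type`), `sample`, `cell_type`,
#'   `cells_per_column`.
#' @export
aggregate_pseudobulk <- function(cells, min_cells = 10L) {
  grp <- paste(cells$cell_sample, cells$cell_type, sep = "|")
  if (length(grp) == 0L) {
    warning("no cells to aggregate", call. = FALSE)
    return(structure(list(
      counts = matrix(0, nrow(cells$counts), 0L,
                      dimnames = list(rownames(cells$counts), NULL)),
      sample = character(0), cell_type = character(0),
      cells_per_column = integer(0)), class = "pseudobulk_matrix"))
  }
  sizes <- table(grp)
  keep_grp <- names(sizes)[sizes >= min_cells]
  keep_grp <- sort(keep_grp)
  ind <- Matrix::sparseMatrix(
    i = seq_along(grp)[grp %in% keep_grp],
    j = match(grp[grp %in% keep_grp], keep_grp),
    x = 1, dims = c(length(grp), length(keep_grp)))
  B <- as.matrix(cells$counts %*% ind)
  dimnames(B) <- list(rownames(cells$counts), keep_grp)
  parts <- strsplit(keep_grp, "|", fixed = TRUE)
  structure(list(counts = B,
                 sample = vapply(parts, `[`, "", 1L),
                 cell_type = vapply(parts, `[`, "", 2L),
                 cells_per_column = stats::setNames(
                   as.integer(sizes[keep_grp]), keep_grp)),
            class = "pseudobulk_matrix")
}

#' @exportS3Method base::print
print.pseudobulk_matrix <- function(x, ...) {
  cat(sprintf("<pseudobulk_matrix> %d genes x %d pseudobulks (%d samples, %d types)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample)), length(unique(x$cell_type))))
  invisible(x)
}

#' Size-factor normalize a pseudobulk matrix
#'
#' Divides each pseudobulk column by its median-of-ratios size factor
#' (see [size_factors_median_of_ratios()]), yielding the
#' normalizedCount layer used for gene set scoring of pseudobulks.
#'
#' @param pb a `pseudobulk_matrix` with >= 2 columns.
#' @return an `expr_matrix` with layer normalizedCount and a
#'   `size_factors` attribute.
#' @export
pseudobulk_normalize <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk_matrix"))
  if (ncol(pb$counts) < 2L)
    stop("need >= 2 pseudobulk columns to normalize", call. = FALSE)
  sf <- size_factors_median_of_ratios(pb$counts)
  out <- expression_matrix(sweep(pb$counts, 2L, sf, "/"),
                           "normalizedCount")
  attr(out, "size_factors") <- sf
  out
}
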
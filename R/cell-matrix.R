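#' Sparse single-cell UMI count container
#'
#' Holds raw UMI counts n_ij for gene i in cell j as a sparse genes x
#' cells matrix, plus the per-cell sample and cell-type/cluster labels
#' and the set of mitochondrial genes used for QC fractions.
#'
#' @param counts a genes x cells matrix (dense or `Matrix` sparse) of
#'   nonnegative integer UMI counts with dimnames.
#' @param cell_sample character vector, named by cell id or in cell
#'   order, mapping each cell to its sample.
#' @param cell_type character vector mapping each cell to its
#'   cell-type/cluster label.
#' @param mito_genes gene ids counted as mitochondrial; defaults to the
#'   genes whose id starts with `mito_prefix`.
#' @param mito_prefix prefix identifying mitochondrial genes when
#'   `mito_genes` is not given (default `"MT-"`).
#' @return an object of class `"cell_matrix"`.
#' @export
cell_matrix <- function(counts, cell_sample, cell_type,
                        mito_genes = NULL, mito_prefix = "MT-") {
  dn <- dimnames(counts)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(dimnames(counts)) && !is.null(dn))
    dimnames(counts) <- dn
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("counts must have gene (row) and cell (column) names",
         call. = FALSE)
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("UMI counts must be nonnegative integers", call. = FALSE)
  cells <- colnames(counts)
  cell_sample <- align_cell_meta(cell_sample, cells, "cell_sample")
  cell_type <- align_cell_meta(cell_type, cells, "cell_type")
  if (is.null(mito_genes))
    mito_genes <- grep(paste0("^", mito_prefix), rownames(counts),
                       value = TRUE)
  mito_genes <- intersect(mito_genes, rownames(counts))
  structure(list(counts = counts, cell_sample = cell_sample,
                 cell_type = cell_type, mito_genes = mito_genes),
            class = "cell_matrix")
}

align_cell_meta <- function(x, cells, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(cells, names(x))
    if (length(missing))
      stop("cells missing from ", what, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    x <- x[cells]
  } else if (length(x) != length(cells)) {
    stop(what, " must be named by cell id or match the cell count",
         call. = FALSE)
  } else {
    names(x) <- cells
  }
  as.character(x)
}

#' @exportS3Method base::print
print.cell_matrix <- function(x, ...) {
  cat(sprintf(
    "<cell_matrix> %d genes x %d cells, %d samples, %d types, %d mito genes\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$cell_sample)),
    length(unique(x$cell_type)), length(x$mito_genes)))
  invisible(x)
}

#' Per-cell total UMIs
#' @param cells a [cell_matrix()].
#' @return named numeric vector of column sums.
#' @export
cell_totals <- function(cells) Matrix::colSums(cells$counts)

#' Per-cell mitochondrial UMI fraction
#' @param cells a [cell_matrix()].
#' @return named numeric vector in [0, 1] (0 for cells with no UMIs).
#' @export
mito_fraction <- function(cells) {
  tot <- cell_totals(cells)
  mito <- Matrix::colSums(cells$counts[cells$mito_genes, , drop = FALSE])
  ifelse(tot > 0, mito / tot, 0)
}

#' Read a cell x gene UMI matrix with cell metadata
#'
#' @param path counts file: a MatrixMarket `.mtx` triplet file (with
#'   sibling id files `<path>.genes` and `<path>.cells`, one id per
#'   line) or a dense delimited file (genes in rows, cells in columns,
#'   first column gene ids).
#' @param format `"mtx_triplet"` or `"dense_csv"`.
#' @param metadata path to a delimited table with columns `cell_id`,
#'   `sample_id`, `cell_type`. Every cell in the counts must appear;
#'   offenders are listed in the error.
#' @param mito_prefix prefix identifying mitochondrial gene ids.
#' @return a [cell_matrix()].
#' @export
read_cell_matrix <- function(path, format = c("mtx_triplet", "dense_csv"),
                             metadata, mito_prefix = "MT-") {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    m <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".genes"))
    cells <- readLines(paste0(path, ".cells"))
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("id sidecar files do not match matrix dimensions",
           call. = FALSE)
    dimnames(m) <- list(genes, cells)
  } else {
    em <- read_expression(path, layer = "counts")
    m <- unclass(em)
    attr(m, "layer") <- NULL
  }
  sep <- detect_delim(metadata)
  meta <- utils::read.table(metadata, sep = sep, header = TRUE,
                            colClasses = "character")
  need <- c("cell_id", "sample_id", "cell_type")
  if (!all(need %in% names(meta)))
    stop("metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(colnames(m), meta$cell_id)
  if (length(missing))
    stop("cells absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(colnames(m), meta$cell_id)
  cell_matrix(m,
              cell_sample = stats::setNames(meta$sample_id[idx],
                                            colnames(m)),
              cell_type = stats::setNames(meta$cell_type[idx],
                                          colnames(m)),
              mito_prefix = mito_prefix)
}

#' Write a cell matrix as MTX triplets plus metadata
#'
#' Writes `<path>` (MatrixMarket), `<path>.genes`, `<path>.cells` and a
#' metadata CSV, the inverse of [read_cell_matrix()].
#'
#' @param cells a [cell_matrix()].
#' @param path output `.mtx` path.
#' @param metadata output metadata CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_matrix <- function(cells, path, metadata) {
  Matrix::writeMM(cells$counts, path)
  writeLines(rownames(cells$counts), paste0(path, ".genes"))
  writeLines(colnames(cells$counts), paste0(path, ".cells"))
  utils::write.table(
    data.frame(cell_id = colnames(cells$counts),
               sample_id = cells$cell_sample,
               cell_type = cells$cell_type),
    metadata, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
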
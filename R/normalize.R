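#' Median-of-ratios size factors
#'
#' The reference for each gene is its geometric mean across samples
#' (genes with a zero in any sample are excluded from the reference);
#' each sample's factor is the median, over reference genes, of its
#' count/reference ratio. Identical columns therefore get factor 1.
#'
#' @param counts an `expr_matrix` (counts or normalizedCount) or plain
#'   matrix with >= 2 samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- unclass(counts)
  if (ncol(m) < 2L)
    stop("need >= 2 samples to estimate size factors", call. = FALSE)
  pos <- rowSums(m <= 0) == 0L
  if (!any(pos))
    stop("no gene is positive in every sample; size factors undefined",
         call. = FALSE)
  logm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(logm)                      # log geometric mean
  sf <- apply(logm, 2L, function(col) exp(stats::median(col - ref)))
  stats::setNames(sf, colnames(m))
}

#' nRPKM: normalized reads per kilobase gene model per million reads
#'
#' Counts are first scaled by a per-sample factor — median-of-ratios
#' size factors by default, or the raw library size in millions when
#' `use_size_factors = FALSE` — then divided by the exonic gene-model
#' length in kb and by the library size in millions. Genes without a
#' length are dropped with a warning.
#'
#' @param counts an `expr_matrix` with layer counts.
#' @param exonic_length_bp named numeric vector of exonic model lengths
#'   in bp (> 0).
#' @param use_size_factors apply median-of-ratios size factors before
#'   the per-kb/per-million scaling (default TRUE; requires >= 2
#'   samples, otherwise the factor is 1).
#' @return an `expr_matrix` with layer nrpkm.
#' @export
compute_nrpkm <- function(counts, exonic_length_bp,
                          use_size_factors = TRUE) {
  assert_layer(counts, "counts", "compute_nrpkm")
  m <- unclass(counts)
  have <- rownames(m) %in% names(exonic_length_bp)
  if (!all(have)) {
    warning(sum(!have), " gene(s) without exonic length dropped: ",
            paste(utils::head(rownames(m)[!have], 5L), collapse = ", "),
            call. = FALSE)
    m <- m[have, , drop = FALSE]
  }
  len <- exonic_length_bp[rownames(m)]
  if (any(len <= 0)) stop("exonic lengths must be > 0", call. = FALSE)
  sf <- if (use_size_factors && ncol(m) >= 2L)
    size_factors_median_of_ratios(m) else rep(1, ncol(m))
  total <- colSums(unclass(counts))          # raw library size
  vals <- sweep(m, 2L, sf, "/")
  vals <- vals / (len / 1000)
  vals <- sweep(vals, 2L, total / 1e6, "/")
  expression_matrix(vals, "nrpkm")
}

#' Log-stabilize expression values as log2(x + 1)
#'
#' @param m an `expr_matrix` with nonnegative values (counts, nrpkm or
#'   normalizedCount layer).
#' @return an `expr_matrix` with layer log2stab.
#' @export
log_stabilize <- function(m) {
  assert_layer(m, c("counts", "nrpkm", "normalizedCount"),
               "log_stabilize")
  if (any(unclass(m) < 0))
    stop("log_stabilize requires nonnegative values", call. = FALSE)
  expression_matrix(log2(unclass(m) + 1), "log2stab")
}

#' Total-transcript normalization of cell UMI counts
#'
#' Rescales each cell's counts so that its column sum equals
#' `target_total`, preserving within-cell gene proportions exactly.
#'
#' @param cells a [cell_matrix()]; every cell must have > 0 UMIs.
#' @param target_total positive target column sum; defaults to the
#'   median cell depth.
#' @return a `cell_matrix` whose counts slot holds real values.
#' @export
total_transcript_normalize <- function(cells, target_total = NULL) {
  tot <- cell_totals(cells)
  if (any(tot <= 0))
    stop("zero-count cell(s) present (QC-filter first): ",
         paste(names(tot)[tot <= 0], collapse = ", "), call. = FALSE)
  if (is.null(target_total)) target_total <- stats::median(tot)
  stopifnot(target_total > 0)
  out <- cells
  out$counts <- cells$counts %*%
    Matrix::Diagonal(length(tot), target_total / tot)
  dimnames(out$counts) <- dimnames(cells$counts)
  out
}

#' Row-wise Z scores
#'
#' Each gene's values become distances from its mean across samples in
#' units of its (n-1 denominator) standard deviation. Zero-variance
#' rows are set to all zeros with a warning.
#'
#' @param m an `expr_matrix` with >= 2 samples.
#' @return an `expr_matrix` with layer centered.
#' @export
zscore_rows <- function(m) {
  v <- unclass(m)
  if (ncol(v) < 2L)
    stop("Z scores need >= 2 samples", call. = FALSE)
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  z <- (v - mu) / sd
  flat <- sd == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) set to 0", call. = FALSE)
    z[flat, ] <- 0
  }
  attr(z, "layer") <- NULL
  expression_matrix(z, "centered")
}

#' Most variable genes by interquartile range
#'
#' Ranks genes by the IQR of their values across samples (descending),
#' breaking ties by gene id in C-locale lexicographic order, and
#' returns the top `n` ids — the preprocessing used before PCA of
#' expression cohorts.
#'
#' @param m an `expr_matrix`.
#' @param n number of genes to return (1 <= n <= nrow).
#' @return character vector of `n` gene ids.
#' @export
top_variable_genes_iqr <- function(m, n) {
  v <- unclass(m)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (n > nrow(v)) stop("n exceeds gene count", call. = FALSE)
  iqr <- apply(v, 1L, stats::IQR, type = 7)
  ord <- order(-iqr, rownames(v), method = "radix")
  rownames(v)[ord][seq_len(n)]
}
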
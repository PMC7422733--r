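#' Expression matrix with a declared layer
#'
#' A genes x samples numeric matrix carrying a `layer` attribute that
#' records what the values are: raw `counts`, `nrpkm` (normalized reads
#' per kilobase gene model per million total reads), `normalizedCount`
#' (size-factor-normalized counts), `log2stab` (log2(x + 1) stabilized
#' values) or `centered` (control-centered log-scale values). Downstream
#' operations check the layer so that, e.g., gene set scores can only be
#' computed from centered values.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames.
#' @param layer one of `"counts"`, `"nrpkm"`, `"normalizedCount"`,
#'   `"log2stab"`, `"centered"`.
#' @return a numeric matrix of class `"expr_matrix"` with a `layer`
#'   attribute.
#' @export
expression_matrix <- function(values, layer = c("counts", "nrpkm",
                                                "normalizedCount",
                                                "log2stab", "centered")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (layer == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("counts layer must contain nonnegative integers", call. = FALSE)
  } else if (layer %in% c("nrpkm", "normalizedCount")) {
    if (any(values < 0))
      stop(layer, " layer must be nonnegative", call. = FALSE)
  }
  structure(values, layer = layer, class = c("expr_matrix", class(values)))
}

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, layer = %s\n",
              nrow(x), ncol(x), attr(x, "layer")))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE],
                    6L))
  invisible(x)
}

#' Layer of an expression matrix
#' @param m an `expr_matrix`.
#' @return the layer string.
#' @export
expr_layer <- function(m) {
  lay <- attr(m, "layer")
  if (is.null(lay)) stop("not an expr_matrix: no layer attribute",
                         call. = FALSE)
  lay
}

assert_layer <- function(m, allowed, what) {
  lay <- expr_layer(m)
  if (!lay %in% allowed)
    stop(sprintf("%s expects layer %s, got '%s'", what,
                 paste(sQuote(allowed), collapse = " or "), lay),
         call. = FALSE)
  invisible(lay)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  n_comma <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  if (n_comma > 0L && n_tab > 0L)
    stop("ambiguous delimiter in ", path,
         ": header contains both commas and tabs", call. = FALSE)
  if (n_comma == 0L && n_tab == 0L)
    stop("could not detect delimiter in ", path,
         ": header contains neither comma nor tab", call. = FALSE)
  if (n_comma > 0L) "," else "\t"
}

#' Read a delimited expression matrix
#'
#' First column holds gene ids, header row holds sample ids. The
#' delimiter is auto-detected (comma or tab); files whose header mixes
#' both are rejected rather than guessed.
#'
#' @param path path to a delimited text file.
#' @param layer declared layer of the stored values (see
#'   [expression_matrix()]).
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, layer = "counts") {
  sep <- detect_delim(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L)
    stop("malformed header in ", path, ": need gene id column plus ",
         "at least one sample column", call. = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num) && !all(is.na(num) == (vals %in% c("NA", "")))) {
    bad <- which(is.na(num) & !vals %in% c("NA", ""), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                 vals[bad[1L], bad[2L]], genes[bad[1L]],
                 colnames(vals)[bad[2L]], path), call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(vals))
  expression_matrix(num, layer = layer)
}

#' Write an expression matrix as delimited text
#'
#' @param m an `expr_matrix`.
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, sep = ",") {
  df <- data.frame(gene_id = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Checks the per-sample covariate table used throughout the package:
#' unique `sample_id`, `diagnosis` in {control, AD}, nonnegative `age`
#' and `pmi`, `braak` in 0..6 when present.
#'
#' @param df a data.frame with at least `sample_id` and `diagnosis`.
#' @return `df`, with `diagnosis` as a factor leveled control, AD.
#' @export
sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("sample_id", "diagnosis") %in% names(df)))
    stop("sample table needs `sample_id` and `diagnosis` columns",
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (!all(df$diagnosis %in% c("control", "AD")))
    stop("diagnosis must be 'control' or 'AD'", call. = FALSE)
  df$diagnosis <- factor(df$diagnosis, levels = c("control", "AD"))
  if (!is.null(df$age) && any(df$age < 0, na.rm = TRUE))
    stop("age must be >= 0", call. = FALSE)
  if (!is.null(df$pmi) && any(df$pmi < 0, na.rm = TRUE))
    stop("pmi must be >= 0", call. = FALSE)
  if (!is.null(df$braak) &&
      any(df$braak < 0 | df$braak > 6, na.rm = TRUE))
    stop("braak must be in 0..6", call. = FALSE)
  df
}
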
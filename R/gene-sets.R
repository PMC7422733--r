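#' Construct a gene set
#'
#' A named list of member genes with a per-gene direction weight in
#' {+1, -1}. A "plain" set (used for ordinary gene set scores) has all
#' weights +1; signed sets (e.g. combined up/down DE signatures) carry
#' -1 for down genes so that down-regulation contributes positively to
#' the signed DE score.
#'
#' @param name set name.
#' @param members character vector of unique gene ids.
#' @param direction numeric vector of +1/-1, recycled if length 1;
#'   may be named by gene id.
#' @return an object of class `"gene_set"`.
#' @export
gene_set <- function(name, members, direction = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(members))
  if (anyDuplicated(members))
    stop("gene set '", name, "' has duplicate members", call. = FALSE)
  if (length(direction) == 1L)
    direction <- rep(direction, length(members))
  if (length(direction) != length(members))
    stop("direction length must match members", call. = FALSE)
  if (!all(direction %in% c(-1, 1)))
    stop("directions must be +1 or -1", call. = FALSE)
  names(direction) <- members
  structure(list(name = name, members = members, direction = direction),
            class = "gene_set")
}

#' @exportS3Method base::print
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes (%d up, %d down)\n", x$name,
              length(x$members), sum(x$direction > 0),
              sum(x$direction < 0)))
  invisible(x)
}

#' Read gene sets from GMT or two-column text
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; all
#' directions default to +1. The two-column format is one set per file
#' (named after the file), rows `gene<delim>direction` with direction
#' tokens `+1`/`1`/`-1`. Empty sets are skipped with a warning.
#'
#' @param path input file.
#' @param format `"gmt"` or `"two_column"`.
#' @return a named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path, format = c("gmt", "two_column")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 2L)
        stop("malformed GMT line (need name and description): ", ln,
             call. = FALSE)
      members <- parts[-(1:2)]
      members <- members[nzchar(members)]
      if (length(members) == 0L) {
        warning("gene set '", parts[1L], "' is empty; skipped",
                call. = FALSE)
        next
      }
      sets[[parts[1L]]] <- gene_set(parts[1L], members)
    }
    sets
  } else {
    sep <- detect_delim(path)
    df <- utils::read.table(path, sep = sep, header = FALSE,
                            col.names = c("gene", "direction"),
                            colClasses = "character")
    dir <- ifelse(df$direction %in% c("+1", "1"), 1,
                  ifelse(df$direction == "-1", -1, NA_real_))
    if (anyNA(dir))
      stop("unknown direction token: ",
           paste(unique(df$direction[is.na(dir)]), collapse = ", "),
           call. = FALSE)
    nm <- sub("\\.[^.]*$", "", basename(path))
    if (nrow(df) == 0L) {
      warning("gene set '", nm, "' is empty; skipped", call. = FALSE)
      return(list())
    }
    stats::setNames(list(gene_set(nm, df$gene, dir)), nm)
  }
}

#' Write gene sets to a GMT file
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$members), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
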
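#' Validate a long-format qPCR plate
#'
#' Records of (sample, assay, replicate, Ct, quality). Ct values are
#' positive cycles or the non-detection sentinel 999; quality is a
#' nonnegative numeric with quality > 0 meaning a usable reading.
#'
#' @param df data.frame with columns `sample_id`, `assay_id`,
#'   `replicate`, `ct`, `quality`.
#' @return `df` with class `"qpcr_plate"` prepended.
#' @export
qpcr_plate <- function(df) {
  need <- c("sample_id", "assay_id", "replicate", "ct", "quality")
  if (!all(need %in% names(df)))
    stop("qPCR plate needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$ct <= 0 & df$ct != 999))
    stop("ct must be positive cycles or the sentinel 999",
         call. = FALSE)
  if (any(df$quality < 0))
    stop("quality must be >= 0", call. = FALSE)
  if (!inherits(df, "qpcr_plate"))
    class(df) <- c("qpcr_plate", class(df))
  df
}

#' Read/write a qPCR plate as CSV
#' @param path CSV with the [qpcr_plate()] columns.
#' @return a `qpcr_plate`.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qpcr_plate(df)
}

#' @rdname read_qpcr
#' @param plate a `qpcr_plate`.
#' @return `path`, invisibly.
#' @export
write_qpcr <- function(plate, path) {
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Detection-ceiling imputation of Ct values
#'
#' Per assay, the maximum reliable Ct (maxCt) is taken over quality > 0
#' records (the 999 sentinel never counts as a reliable reading); every
#' record with Ct above maxCt — including 999 non-detections — is
#' assigned maxCt + 0.5. Assays with no quality > 0 record are dropped
#' with a warning. Idempotent: a second application changes nothing.
#'
#' @param plate a [qpcr_plate()].
#' @return the imputed `qpcr_plate`.
#' @export
impute_ceiling <- function(plate) {
  plate <- qpcr_plate(plate)
  out <- NULL
  for (assay in unique(plate$assay_id)) {
    rows <- plate[plate$assay_id == assay, , drop = FALSE]
    usable <- rows$quality > 0 & rows$ct != 999
    if (!any(usable)) {
      warning("assay '", assay, "' has no quality > 0 record; dropped",
              call. = FALSE)
      next
    }
    maxct <- max(rows$ct[usable])
    high <- rows$ct > maxct
    rows$ct[high] <- maxct + 0.5
    out <- rbind(out, rows)
  }
  qpcr_plate(out)
}

#' Collapse duplicate wells to one Ct per sample and assay
#'
#' Duplicate pairs whose absolute Ct difference is at most
#' `max_abs_diff` are averaged; pairs differing by more are discarded
#' outright (a pair differing by exactly 2.82 has a standard deviation
#' of 2.82 / sqrt(2), about 2 cycles — the motivation for the default).
#' Singleton replicates are kept as-is. More than 2 replicates per
#' (sample, assay) is an error.
#'
#' @param plate a [qpcr_plate()] (typically after [impute_ceiling()]).
#' @param max_abs_diff maximum tolerated |Ct1 - Ct2| (default 2.82).
#' @return a `qpcr_plate` with one record per kept (sample, assay);
#'   discarded pairs (with both Cts) in the `discarded` attribute.
#' @export
collapse_duplicates <- function(plate, max_abs_diff = 2.82) {
  plate <- qpcr_plate(plate)
  key <- interaction(plate$sample_id, plate$assay_id, drop = TRUE)
  pieces <- split(seq_len(nrow(plate)), key)
  kept <- list(); disc <- list()
  for (idx in pieces) {
    rows <- plate[idx, , drop = FALSE]
    if (nrow(rows) > 2L)
      stop("more than 2 replicates for sample '", rows$sample_id[1L],
           "', assay '", rows$assay_id[1L], "'", call. = FALSE)
    if (nrow(rows) == 2L &&
        abs(diff(rows$ct)) > max_abs_diff + 1e-9) {
      disc[[length(disc) + 1L]] <-
        data.frame(sample_id = rows$sample_id[1L],
                   assay_id = rows$assay_id[1L],
                   ct1 = rows$ct[1L], ct2 = rows$ct[2L])
      next
    }
    kept[[length(kept) + 1L]] <-
      data.frame(sample_id = rows$sample_id[1L],
                 assay_id = rows$assay_id[1L], replicate = 1L,
                 ct = mean(rows$ct), quality = min(rows$quality))
  }
  if (length(kept) == 0L)
    stop("all sample/assay pairs discarded", call. = FALSE)
  out <- qpcr_plate(do.call(rbind, kept))
  attr(out, "discarded") <- if (length(disc)) do.call(rbind, disc)
                            else NULL
  out
}

#' Global-median delta-Ct normalization
#'
#' For each sample, the median Ct over all of its assays (the "global
#' median") is subtracted from every assay's Ct. Lower delta-Ct means
#' higher expression. Samples with fewer than 3 assays trigger a
#' warning (the median is unstable).
#'
#' @param plate a collapsed [qpcr_plate()] (one record per
#'   sample/assay).
#' @return a data.frame of class `"delta_ct_table"`: `sample_id`,
#'   `assay_id`, `delta_ct`, with the per-sample medians in the
#'   `global_median` attribute.
#' @export
delta_ct <- function(plate) {
  plate <- qpcr_plate(plate)
  if (anyDuplicated(paste(plate$sample_id, plate$assay_id)))
    stop("plate must be collapsed to one record per sample/assay",
         call. = FALSE)
  med <- tapply(plate$ct, plate$sample_id, stats::median)
  n_assay <- table(plate$sample_id)
  if (any(n_assay < 3L))
    warning("sample(s) with < 3 assays; global median unstable: ",
            paste(names(n_assay)[n_assay < 3L], collapse = ", "),
            call. = FALSE)
  out <- data.frame(sample_id = plate$sample_id,
                    assay_id = plate$assay_id,
                    delta_ct = plate$ct -
                      as.numeric(med[plate$sample_id]))
  structure(out, global_median = med,
            class = c("delta_ct_table", "data.frame"))
}

#' Per-assay group differential expression on delta-Ct values
#'
#' Fits the per-assay linear model `~ group` on the expression-scale
#' values -delta-Ct, so a positive effect means higher expression in
#' the second group (AD), directly comparable in sign to RNA-seq log2
#' fold changes. p values are BH-adjusted across assays.
#'
#' @param dct a [delta_ct()] table.
#' @param groups a [sample_table()] covering the samples.
#' @param group_col grouping column (default "diagnosis").
#' @return a `de_fit` data.frame, one row per assay (the `gene` column
#'   holds assay ids; effects are on the -delta-Ct scale).
#' @export
qpcr_group_de <- function(dct, groups, group_col = "diagnosis") {
  stopifnot(inherits(dct, "delta_ct_table"))
  wide <- stats::xtabs(delta_ct ~ assay_id + sample_id, data = dct)
  present <- table(dct$assay_id, dct$sample_id) > 0
  if (!all(present))
    wide[!present] <- NA
  m <- -as.matrix(unclass(wide))              # expression scale
  keep <- rowSums(is.na(m)) == 0L
  if (!all(keep)) {
    warning(sum(!keep), " assay(s) with missing samples dropped",
            call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  fml <- stats::as.formula(paste("~", group_col))
  fit_gene_linear_models(m, fml, groups)
}
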
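# Small in-code fixtures shared across test files.

toy_expr <- function(values, layer = "counts",
                     genes = sprintf("g%d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, layer)
}

toy_centered <- function(values, ...)
  toy_expr(values * 1.0, layer = "centered", ...)

toy_samples <- function(n_control, n_ad, prefix = "s") {
  sample_table(data.frame(
    sample_id = sprintf("%s%02d", prefix, seq_len(n_control + n_ad)),
    diagnosis = rep(c("control", "AD"), c(n_control, n_ad)),
    stringsAsFactors = FALSE))
}

# cell_matrix built from a dense integer matrix, round-robin samples
toy_cells <- function(counts, samples = "sampA", types = "typeA",
                      mito_prefix = "MT-") {
  n <- ncol(counts)
  cell_matrix(counts,
              cell_sample = rep_len(samples, n),
              cell_type = rep_len(types, n),
              mito_prefix = mito_prefix)
}

# a score_table built directly from values (bypassing scoring)
new_score_table_for_test <- function(sample_id, score,
                                     set = "test_set") {
  structure(data.frame(sample_id = sample_id, score = score,
                       row.names = NULL),
            gene_set_name = set, n_genes_used = NA_integer_,
            dataset_label = NA_character_,
            class = c("score_table", "data.frame"))
}

# collapsed qPCR plate from a wide sample x assay Ct matrix
toy_plate <- function(ct_by_sample, quality = 1) {
  rows <- do.call(rbind, lapply(names(ct_by_sample), function(s) {
    ct <- ct_by_sample[[s]]
    data.frame(sample_id = s, assay_id = names(ct), replicate = 1L,
               ct = unname(ct), quality = quality)
  }))
  qpcr_plate(rows)
}
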
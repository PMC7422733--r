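#' Center log-scale expression on a dataset's control samples
#'
#' Subtracts, per gene, the mean log-stabilized expression of the
#' dataset's control samples from every sample, yielding the
#' control-centered values that gene set scores average over. Centering
#' is always per dataset: never center samples from different studies
#' against a shared control mean.
#'
#' @param logm an `expr_matrix` with layer log2stab.
#' @param control_ids nonempty character vector of control sample ids
#'   present in `logm`.
#' @return an `expr_matrix` with layer centered.
#' @export
control_center <- function(logm, control_ids) {
  assert_layer(logm, c("log2stab", "centered"), "control_center")
  if (length(control_ids) == 0L)
    stop("control set is empty", call. = FALSE)
  missing <- setdiff(control_ids, colnames(logm))
  if (length(missing))
    stop("control ids absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  v <- unclass(logm)
  ctrl_mean <- rowMeans(v[, control_ids, drop = FALSE])
  z <- v - ctrl_mean
  attr(z, "layer") <- NULL
  expression_matrix(z, "centered")
}

new_score_table <- function(sample_id, score, set, n_used, dataset) {
  structure(data.frame(sample_id = sample_id, score = score,
                       row.names = NULL),
            gene_set_name = set, n_genes_used = n_used,
            dataset_label = dataset,
            class = c("score_table", "data.frame"))
}

score_members <- function(centered, set, signed, dataset) {
  assert_layer(centered, "centered", "gene set scoring")
  present <- intersect(set$members, rownames(centered))
  if (length(present) == 0L)
    stop("no member of gene set '", set$name,
         "' is present in the matrix", call. = FALSE)
  absent <- setdiff(set$members, present)
  if (length(absent))
    message("gene set '", set$name, "': ", length(absent),
            " member(s) absent from matrix")
  v <- unclass(centered)[present, , drop = FALSE]
  w <- if (signed) set$direction[present] else rep(1, length(present))
  new_score_table(colnames(centered), colMeans(v * w), set$name,
                  length(present), dataset)
}

#' Gene set score: mean control-centered expression over a set
#'
#' For each sample, the unweighted average of the control-centered
#' log-scale expression values over the set members present in the
#' matrix (absent members are dropped, not imputed; the number used is
#' recorded). By construction the mean score over the centering
#' controls is 0.
#'
#' @param centered an `expr_matrix` with layer centered.
#' @param set a [gene_set()].
#' @param dataset_label optional dataset tag carried on the result.
#' @return a `score_table` data.frame (sample_id, score) with
#'   attributes `gene_set_name`, `n_genes_used`, `dataset_label`.
#' @export
gene_set_score <- function(centered, set, dataset_label = NA_character_)
  score_members(centered, set, signed = FALSE, dataset = dataset_label)

#' Signed DE score
#'
#' Like [gene_set_score()] but each member contributes with its
#' direction weight: up genes +1, down genes -1, so that coordinated
#' up- and down-regulation of a DE signature accumulates in a single
#' score. With all-+1 directions this is identical to
#' [gene_set_score()].
#'
#' @inheritParams gene_set_score
#' @return a `score_table`.
#' @export
de_score <- function(centered, set, dataset_label = NA_character_)
  score_members(centered, set, signed = TRUE, dataset = dataset_label)

#' Restrict gene sets to genes shared by all datasets
#'
#' For cross-study score comparisons, each set is intersected with the
#' intersection of all datasets' gene universes; sets emptied by the
#' restriction are kept (size 0 is reported) with a warning.
#'
#' @param sets list of [gene_set()] objects.
#' @param datasets list of `expr_matrix` objects (>= 1).
#' @return list of restricted gene sets, in the input order.
#' @export
restrict_to_shared_genes <- function(sets, datasets) {
  if (length(datasets) == 0L)
    stop("need at least one dataset", call. = FALSE)
  shared <- Reduce(intersect, lapply(datasets, rownames))
  lapply(sets, function(s) {
    keep <- s$members %in% shared
    if (!any(keep))
      warning("gene set '", s$name,
              "' has no members shared across datasets", call. = FALSE)
    structure(list(name = s$name, members = s$members[keep],
                   direction = s$direction[keep]), class = "gene_set")
  })
}

#' Remove genes from a gene set
#'
#' Used e.g. to drop neuronal-enriched genes before scoring whole
#' tissue (mitigating neuronal-loss confounding) or to remove APOE
#' from activation signatures.
#'
#' @param set a [gene_set()].
#' @param exclusion character vector of gene ids to remove.
#' @return the reduced gene set (a warning if emptied).
#' @export
exclude_genes <- function(set, exclusion) {
  keep <- !set$members %in% exclusion
  if (!any(keep))
    warning("gene set '", set$name, "' emptied by exclusion",
            call. = FALSE)
  structure(list(name = set$name, members = set$members[keep],
                 direction = set$direction[keep]), class = "gene_set")
}

#' Balance diagnosis groups across bins of myeloid score
#'
#' Samples are split into `n_bins` bins of similar myeloid gene set
#' score (equal-count quantile bins by default, ties to the lower bin;
#' equal-width optional). Bins containing only one diagnosis group are
#' discarded wholly; in each remaining bin, samples of the
#' over-represented group are removed uniformly at random (seeded)
#' until the bin's AD fraction is as close as achievable to the AD
#' fraction of the samples surviving the single-group-bin drop.
#' Balancing only ever discards samples.
#'
#' @param scores a `score_table` of myeloid scores for all samples.
#' @param diagnosis a [sample_table()] covering the scored samples.
#' @param n_bins number of bins (default 20).
#' @param seed required integer seed for the random discards.
#' @param method `"quantile"` (equal-count, default) or `"width"`
#'   (equal-width bins).
#' @return an object of class `"balance_plan"`: fields `n_bins`,
#'   `method`, `bin_edges`, `assignments` (per-sample bin, diagnosis,
#'   kept flag), `kept_sample_ids`, `discarded_sample_ids`,
#'   `target_fraction`, `seed`.
#' @export
myeloid_balance <- function(scores, diagnosis, n_bins = 20L, seed,
                            method = c("quantile", "width")) {
  method <- match.arg(method)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  d <- merge(as.data.frame(scores),
             diagnosis[, c("sample_id", "diagnosis")], by = "sample_id")
  if (nrow(d) != nrow(scores))
    stop("diagnosis table does not cover all scored samples",
         call. = FALSE)
  if (length(unique(d$diagnosis)) < 2L)
    stop("both diagnosis groups must be present", call. = FALSE)
  edges <- if (method == "quantile")
    stats::quantile(d$score, probs = seq(0, 1, length.out = n_bins + 1L),
                    type = 7, names = FALSE)
  else seq(min(d$score), max(d$score), length.out = n_bins + 1L)
  inner <- unique(edges[-c(1L, length(edges))])
  d$bin <- findInterval(d$score, inner, left.open = TRUE) + 1L
  d$kept <- TRUE

  # drop bins where only one group is present, then match the rest to
  # the AD fraction among the survivors
  tab <- table(factor(d$bin), d$diagnosis)
  mixed <- rownames(tab)[tab[, "control"] > 0 & tab[, "AD"] > 0]
  d$kept[!d$bin %in% as.integer(mixed)] <- FALSE
  if (!any(d$kept))
    stop("no bin contains both diagnosis groups", call. = FALSE)
  target <- mean(d$diagnosis[d$kept] == "AD")

  set.seed(seed)
  for (b in as.integer(mixed)) {
    idx <- which(d$bin == b & d$kept)
    a <- sum(d$diagnosis[idx] == "AD")
    c_ <- length(idx) - a
    over <- if (a / (a + c_) > target) "AD" else "control"
    n_over <- if (over == "AD") a else c_
    n_other <- (a + c_) - n_over
    frac <- function(k) {
      ad_k <- if (over == "AD") k else n_other
      tot <- k + n_other
      ad_k / tot
    }
    k_best <- which.min(abs(vapply(seq_len(n_over), frac,
                                   numeric(1)) - target))
    if (k_best < n_over) {
      pool <- idx[d$diagnosis[idx] == over]
      drop <- pool[sample.int(length(pool), n_over - k_best)]
      d$kept[drop] <- FALSE
    }
  }
  structure(list(n_bins = n_bins, method = method, bin_edges = edges,
                 assignments = d[, c("sample_id", "score", "diagnosis",
                                     "bin", "kept")],
                 kept_sample_ids = d$sample_id[d$kept],
                 discarded_sample_ids = d$sample_id[!d$kept],
                 target_fraction = target, seed = seed),
            class = "balance_plan")
}

#' @exportS3Method base::print
print.balance_plan <- function(x, ...) {
  cat(sprintf(
    "<balance_plan> %d bins (%s): kept %d, discarded %d (target AD fraction %.3f)\n",
    x$n_bins, x$method, length(x$kept_sample_ids),
    length(x$discarded_sample_ids), x$target_fraction))
  invisible(x)
}

#' Subset a score table to selected samples
#'
#' Keeps the score-table attributes (set name, genes used, dataset),
#' e.g. when applying a [myeloid_balance()] plan's kept samples.
#'
#' @param scores a `score_table`.
#' @param sample_ids samples to keep.
#' @return the subset `score_table`.
#' @export
subset_scores <- function(scores, sample_ids) {
  d <- as.data.frame(scores)
  d <- d[d$sample_id %in% sample_ids, , drop = FALSE]
  new_score_table(d$sample_id, d$score, attr(scores, "gene_set_name"),
                  attr(scores, "n_genes_used"),
                  attr(scores, "dataset_label"))
}

#' Compare mean scores between two groups
#'
#' Delta is mean(second group) - mean(first group) of the score (log2
#' scale), with a two-sided t test: Student's pooled-variance by
#' default (Welch selectable). Degenerate inputs: both groups constant
#' and equal gives p = 1; a group with fewer than 2 samples yields the
#' delta with p = NA and a warning (the single-control-dataset case).
#'
#' @param scores a `score_table`.
#' @param groups a [sample_table()] (or any data.frame with sample_id
#'   plus the grouping column).
#' @param group_col name of the grouping column (default "diagnosis");
#'   its first factor level (or sorted unique value) is the baseline
#'   group A.
#' @param variant `"student"` or `"welch"`.
#' @return an object of class `"group_comparison"`: `delta`,
#'   `p_value`, `group_sizes`, `groups`, `variant`.
#' @export
compare_groups <- function(scores, groups, group_col = "diagnosis",
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  d <- merge(as.data.frame(scores),
             groups[, c("sample_id", group_col)], by = "sample_id")
  g <- d[[group_col]]
  lev <- if (is.factor(g)) intersect(levels(g), unique(as.character(g)))
         else sort(unique(as.character(g)))
  if (length(lev) != 2L)
    stop("grouping column must have exactly 2 observed levels",
         call. = FALSE)
  x <- d$score[as.character(g) == lev[1L]]
  y <- d$score[as.character(g) == lev[2L]]
  delta <- mean(y) - mean(x)
  p <- if (length(x) < 2L || length(y) < 2L) {
    warning("fewer than 2 samples in a group; p not applicable",
            call. = FALSE)
    NA_real_
  } else if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (delta == 0) 1 else 0
  } else {
    stats::t.test(y, x, var.equal = (variant == "student"))$p.value
  }
  structure(list(delta = delta, p_value = p,
                 group_sizes = stats::setNames(c(length(x), length(y)),
                                               lev),
                 groups = lev, variant = variant),
            class = "group_comparison")
}

#' @exportS3Method base::print
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> delta (%s - %s) = %.4f, p = %s (%s t, n = %d/%d)\n",
              x$groups[2L], x$groups[1L], x$delta,
              format.pval(x$p_value), x$variant,
              x$group_sizes[1L], x$group_sizes[2L]))
  invisible(x)
}

#' Stratify a score table by a metadata column
#'
#' Partitions scores by the given ordered levels (e.g. Braak stage
#' groups) without re-centering. Samples carrying a level not listed
#' raise an error; listed levels with no samples yield empty tables
#' with a warning.
#'
#' @param scores a `score_table`.
#' @param meta a [sample_table()] covering the scored samples.
#' @param by column of `meta` to stratify on.
#' @param levels ordered vector of expected levels.
#' @return named list of `score_table`s, one per level.
#' @export
stratify_scores <- function(scores, meta, by, levels) {
  d <- merge(as.data.frame(scores), meta[, c("sample_id", by)],
             by = "sample_id")
  vals <- as.character(d[[by]])
  unknown <- setdiff(vals, as.character(levels))
  if (length(unknown))
    stop("unknown level(s) in '", by, "': ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  out <- lapply(as.character(levels), function(lv) {
    sub <- d[vals == lv, , drop = FALSE]
    if (nrow(sub) == 0L)
      warning("level '", lv, "' has no samples", call. = FALSE)
    new_score_table(sub$sample_id, sub$score,
                    attr(scores, "gene_set_name"),
                    attr(scores, "n_genes_used"),
                    attr(scores, "dataset_label"))
  })
  stats::setNames(out, as.character(levels))
}
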
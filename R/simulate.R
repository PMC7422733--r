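#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the simulators into one validated list.
#' Defaults mirror the cohorts the package's analyses were designed
#' around: 15 control / 10 AD sorted-microglia profiles, 42 control /
#' 158 AD whole-tissue samples, negative-binomial counts with
#' dispersion 0.1 (variance mu + 0.1 mu^2), and a myeloid mixing weight
#' in whole tissue that is confounded with diagnosis (mean 0.1 in
#' controls vs 0.2 in AD).
#'
#' @param seed integer seed; a fixed seed gives identical output.
#' @param n_genes number of non-mitochondrial genes.
#' @param n_control,n_ad sorted-cohort group sizes.
#' @param wt_n_control,wt_n_ad whole-tissue cohort group sizes.
#' @param cell_types cell-type labels; each receives a marker block.
#' @param markers_per_type genes per marker block.
#' @param marker_fold fold elevation of a marker in its own type.
#' @param base_mean_log mean/sd of log base expression across genes.
#' @param planted_effects named numeric vector of log2 fold changes
#'   (AD vs control) applied to designated genes.
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param myeloid_fraction_params list with `control` and `ad`, each
#'   `c(mean=, sd=)`, for the whole-tissue myeloid mixing weight.
#' @param n_cells number of cells drawn by [simulate_cells()].
#' @param sc_n_control,sc_n_ad numbers of single-cell samples.
#' @param type_props expected cell-type proportions for cell draws.
#' @param depth_lognormal `c(meanlog=, sdlog=)` of per-cell total UMIs.
#' @param mito_fraction_params `c(shape1=, shape2=)` beta parameters of
#'   the per-cell mitochondrial fraction.
#' @param n_mito_genes number of mitochondrial (`MT-`) genes appended.
#' @param qpcr list `(intercept, slope, noise_sd, ceiling)`: replicate
#'   Ct = intercept - slope * log2(expression) + N(0, noise_sd); Ct
#'   above `ceiling` (or zero expression) is recorded as the 999
#'   non-detection sentinel with quality 0.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 400L,
                       n_control = 15L, n_ad = 10L,
                       wt_n_control = 42L, wt_n_ad = 158L,
                       cell_types = c("myeloid", "neuron", "astrocyte",
                                      "endothelial"),
                       markers_per_type = 25L,
                       marker_fold = 16,
                       base_mean_log = c(mean = log(100), sd = 0.8),
                       planted_effects = numeric(0),
                       dispersion = 0.1,
                       myeloid_fraction_params =
                         list(control = c(mean = 0.1, sd = 0.04),
                              ad = c(mean = 0.2, sd = 0.06)),
                       n_cells = 500L,
                       sc_n_control = 2L, sc_n_ad = 2L,
                       type_props = NULL,
                       depth_lognormal = c(meanlog = log(1500),
                                           sdlog = 0.6),
                       mito_fraction_params = c(shape1 = 2,
                                                shape2 = 38),
                       n_mito_genes = 13L,
                       qpcr = list(intercept = 28, slope = 1,
                                   noise_sd = 0.15, ceiling = 26)) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_genes >= length(cell_types) * markers_per_type,
            n_control >= 2L, n_ad >= 2L, dispersion >= 0,
            all(is.finite(planted_effects)))
  for (g in c("control", "ad")) {
    p <- myeloid_fraction_params[[g]]
    if (p[["mean"]] < 0 || p[["mean"]] > 1)
      stop("myeloid fraction mean must be in [0, 1]", call. = FALSE)
  }
  if (is.null(type_props))
    type_props <- stats::setNames(rep(1 / length(cell_types),
                                      length(cell_types)), cell_types)
  genes <- sprintf("g%04d", seq_len(n_genes))
  mito <- if (n_mito_genes > 0L)
    sprintf("MT-%02d", seq_len(n_mito_genes)) else character(0)
  markers <- split(genes[seq_len(length(cell_types) * markers_per_type)],
                   rep(cell_types, each = markers_per_type))
  unknown <- setdiff(names(planted_effects), c(genes, mito))
  if (length(unknown))
    stop("planted_effects name genes outside the simulated universe: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 genes = genes, mito_genes = mito,
                 n_control = n_control, n_ad = n_ad,
                 wt_n_control = wt_n_control, wt_n_ad = wt_n_ad,
                 cell_types = cell_types, markers = markers,
                 marker_fold = marker_fold,
                 base_mean_log = base_mean_log,
                 planted_effects = planted_effects,
                 dispersion = dispersion,
                 myeloid_fraction_params = myeloid_fraction_params,
                 n_cells = n_cells, sc_n_control = sc_n_control,
                 sc_n_ad = sc_n_ad, type_props = type_props,
                 depth_lognormal = depth_lognormal,
                 mito_fraction_params = mito_fraction_params,
                 qpcr = qpcr),
            class = "sim_config")
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Base per-gene mean profile for one cell type: lognormal baseline with
# the type's marker block elevated and other types' markers suppressed.
type_profile <- function(config, type, base) {
  mu <- base
  for (ct in config$cell_types) {
    idx <- match(config$markers[[ct]], names(base))
    mu[idx] <- if (ct == type) mu[idx] * config$marker_fold
               else mu[idx] / config$marker_fold
  }
  mu
}

sim_metadata <- function(ids, diagnosis, region, cell_type) {
  sample_table(data.frame(
    sample_id = ids,
    diagnosis = diagnosis,
    age = round(pmax(60, stats::rnorm(length(ids), 80, 8))),
    sex = sample(c("M", "F"), length(ids), replace = TRUE),
    pmi = round(pmax(1, stats::rgamma(length(ids), shape = 9,
                                      scale = 1 / 3)), 2),
    apoe4 = stats::rbinom(length(ids), 1,
                          ifelse(diagnosis == "AD", 0.5, 0.1)) == 1,
    braak = ifelse(diagnosis == "AD", sample(5:6, length(ids), TRUE),
                   sample(0:3, length(ids), TRUE)),
    region = region, cell_type = cell_type,
    stringsAsFactors = FALSE))
}

#' Simulate a sorted-cell bulk RNA-seq cohort
#'
#' Draws negative-binomial counts for sorted profiles of one cell type
#' (default myeloid): marker genes of that type elevated, other types'
#' markers suppressed, and the configured planted log2 fold changes
#' applied multiplicatively to the AD group means. Metadata (age, sex,
#' PMI, ApoE4, Braak) is drawn from realistic cohort distributions.
#'
#' @param config a [sim_config()].
#' @param sorted_type which cell type the profiles represent.
#' @return list with `counts` (an `expr_matrix`, layer counts),
#'   `samples` (metadata table) and `truth` (planted log2 fold
#'   changes).
#' @export
simulate_sorted_counts <- function(config, sorted_type = "myeloid") {
  stopifnot(inherits(config, "sim_config"),
            sorted_type %in% config$cell_types)
  set.seed(config$seed)
  genes <- c(config$genes, config$mito_genes)
  base <- stats::setNames(
    stats::rlnorm(length(genes), config$base_mean_log[["mean"]],
                  config$base_mean_log[["sd"]]), genes)
  mu_ctrl <- type_profile(config, sorted_type, base)
  mu_ad <- mu_ctrl
  pe <- config$planted_effects
  mu_ad[names(pe)] <- mu_ad[names(pe)] * 2^pe
  n_c <- config$n_control; n_a <- config$n_ad
  ids <- c(sprintf("ctrl%02d", seq_len(n_c)),
           sprintf("ad%02d", seq_len(n_a)))
  counts <- cbind(
    matrix(rnb(length(genes) * n_c, rep(mu_ctrl, n_c),
               config$dispersion), ncol = n_c),
    matrix(rnb(length(genes) * n_a, rep(mu_ad, n_a),
               config$dispersion), ncol = n_a))
  dimnames(counts) <- list(genes, ids)
  samples <- sim_metadata(ids, rep(c("control", "AD"), c(n_c, n_a)),
                          region = "SFG", cell_type = sorted_type)
  list(counts = expression_matrix(counts, "counts"), samples = samples,
       truth = pe)
}

#' Build per-cell-type mean expression signatures
#'
#' Convenience generator of the `cell_signatures` input of
#' [simulate_whole_tissue()]: one column of expected expression per
#' configured cell type, sharing a common lognormal baseline.
#'
#' @param config a [sim_config()].
#' @return an `expr_matrix` (layer nrpkm), genes x cell types.
#' @export
simulate_cell_signatures <- function(config) {
  set.seed(config$seed + 1013L)
  genes <- c(config$genes, config$mito_genes)
  base <- stats::setNames(
    stats::rlnorm(length(genes), config$base_mean_log[["mean"]],
                  config$base_mean_log[["sd"]]), genes)
  sig <- vapply(config$cell_types,
                function(ct) type_profile(config, ct, base),
                numeric(length(genes)))
  dimnames(sig) <- list(genes, config$cell_types)
  expression_matrix(sig, "nrpkm")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Simulate a whole-tissue cohort with a myeloid-abundance confound
#'
#' Each sample's expected profile is a convex combination of the
#' cell-type signatures: the myeloid weight is drawn from a
#' diagnosis-specific truncated normal (by default higher in AD,
#' planting the cell-composition confound that myeloid balancing is
#' designed to remove), the remaining weight is split evenly over the
#' other types. Planted log2 fold changes are applied to the AD
#' samples' mixed means, then NB noise is added. The drawn myeloid
#' weight is returned as ground truth.
#'
#' @param config a [sim_config()].
#' @param cell_signatures genes x cell-types `expr_matrix`; defaults to
#'   [simulate_cell_signatures()].
#' @return list with `counts`, `samples`, `myeloid_weight` (named by
#'   sample) and `truth`.
#' @export
simulate_whole_tissue <- function(config,
                                  cell_signatures =
                                    simulate_cell_signatures(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(config$cell_types %in% colnames(cell_signatures)))
    stop("cell_signatures must cover all configured cell types",
         call. = FALSE)
  set.seed(config$seed)
  n_c <- config$wt_n_control; n_a <- config$wt_n_ad
  ids <- c(sprintf("wt_ctrl%03d", seq_len(n_c)),
           sprintf("wt_ad%03d", seq_len(n_a)))
  diag <- rep(c("control", "AD"), c(n_c, n_a))
  pc <- config$myeloid_fraction_params$control
  pa <- config$myeloid_fraction_params$ad
  w <- numeric(n_c + n_a)
  w[diag == "control"] <- rtrunc_norm(n_c, pc[["mean"]], pc[["sd"]],
                                      0.01, 0.9)
  w[diag == "AD"] <- rtrunc_norm(n_a, pa[["mean"]], pa[["sd"]],
                                 0.01, 0.9)
  names(w) <- ids
  sig <- unclass(cell_signatures)
  others <- setdiff(colnames(sig), "myeloid")
  pe <- config$planted_effects
  counts <- vapply(seq_along(ids), function(s) {
    mu <- sig[, "myeloid"] * w[s] +
      rowSums(sig[, others, drop = FALSE]) * (1 - w[s]) / length(others)
    if (diag[s] == "AD") mu[names(pe)] <- mu[names(pe)] * 2^pe
    rnb(length(mu), mu, config$dispersion)
  }, numeric(nrow(sig)))
  dimnames(counts) <- list(rownames(sig), ids)
  samples <- sim_metadata(ids, diag, region = "FuG",
                          cell_type = "whole_tissue")
  list(counts = expression_matrix(counts, "counts"), samples = samples,
       myeloid_weight = w, truth = pe)
}

#' Simulate single-cell/nucleus UMI counts
#'
#' Per cell: a sample and cell type are drawn, the total UMI depth is
#' lognormal, a beta-distributed mitochondrial fraction is allocated to
#' the MT- genes, and the remaining UMIs are multinomial over the cell
#' type's expression profile (with planted effects applied to AD
#' samples). The lognormal depth tail puts some cells below the usual
#' QC thresholds by construction.
#'
#' @param config a [sim_config()].
#' @return a [cell_matrix()] with a `truth` attribute (planted
#'   effects).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- c(config$genes, config$mito_genes)
  base <- stats::setNames(
    stats::rlnorm(length(genes), config$base_mean_log[["mean"]],
                  config$base_mean_log[["sd"]]), genes)
  samples <- c(sprintf("sc_ctrl%02d", seq_len(config$sc_n_control)),
               sprintf("sc_ad%02d", seq_len(config$sc_n_ad)))
  s_diag <- stats::setNames(
    rep(c("control", "AD"), c(config$sc_n_control, config$sc_n_ad)),
    samples)
  pe <- config$planted_effects
  profiles <- list()
  for (ct in config$cell_types) {
    p <- type_profile(config, ct, base)
    p[config$mito_genes] <- 0   # mito UMIs allocated separately
    pad <- p
    pad[names(pe)] <- pad[names(pe)] * 2^pe
    profiles[[ct]] <- list(control = p / sum(p), AD = pad / sum(pad))
  }
  n <- config$n_cells
  cell_sample <- sample(samples, n, replace = TRUE)
  cell_type <- sample(config$cell_types, n, replace = TRUE,
                      prob = config$type_props[config$cell_types])
  depth <- pmax(1L, round(stats::rlnorm(
    n, config$depth_lognormal[["meanlog"]],
    config$depth_lognormal[["sdlog"]])))
  mito_f <- stats::rbeta(n, config$mito_fraction_params[["shape1"]],
                         config$mito_fraction_params[["shape2"]])
  counts <- matrix(0L, nrow = length(genes), ncol = n,
                   dimnames = list(genes,
                                   sprintf("cell%05d", seq_len(n))))
  n_mt <- length(config$mito_genes)
  for (j in seq_len(n)) {
    m_umis <- if (n_mt > 0L) stats::rbinom(1L, depth[j], mito_f[j])
              else 0L
    if (m_umis > 0L)
      counts[config$mito_genes, j] <-
        stats::rmultinom(1L, m_umis, rep(1, n_mt))
    pr <- profiles[[cell_type[j]]][[s_diag[cell_sample[j]]]]
    counts[config$genes, j] <-
      stats::rmultinom(1L, depth[j] - m_umis, pr[config$genes])
  }
  out <- cell_matrix(counts, cell_sample = cell_sample,
                     cell_type = cell_type,
                     mito_genes = config$mito_genes)
  attr(out, "truth") <- pe
  attr(out, "sample_diagnosis") <- s_diag
  out
}

#' Simulate a duplicate-well qPCR plate from expression values
#'
#' Each (sample, assay) pair yields two replicate Ct values:
#' `Ct = intercept - slope * log2(expression) + N(0, noise_sd)`.
#' Zero expression, or a Ct above the detection ceiling, is recorded as
#' the sentinel 999 with quality 0 (the convention the downstream
#' ceiling-imputation step expects); detected wells have quality 1.
#'
#' @param config a [sim_config()] (the `qpcr` element is used).
#' @param expression genes(assays) x samples `expr_matrix` of
#'   nonnegative expression values.
#' @return a long-format data.frame of class `"qpcr_plate"` with
#'   columns sample_id, assay_id, replicate, ct, quality.
#' @export
simulate_qpcr <- function(config, expression) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  q <- config$qpcr
  expr <- unclass(expression)
  grid <- expand.grid(assay_id = rownames(expr),
                      sample_id = colnames(expr),
                      replicate = 1:2, stringsAsFactors = FALSE)
  e <- expr[cbind(grid$assay_id, grid$sample_id)]
  ct <- q$intercept - q$slope * log2(pmax(e, .Machine$double.xmin)) +
    stats::rnorm(nrow(grid), 0, q$noise_sd)
  undetected <- e <= 0 | ct > q$ceiling
  plate <- data.frame(sample_id = grid$sample_id,
                      assay_id = grid$assay_id,
                      replicate = grid$replicate,
                      ct = ifelse(undetected, 999, ct),
                      quality = ifelse(undetected, 0, 1))
  qpcr_plate(plate)
}
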
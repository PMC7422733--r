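#' Per-gene ordinary least squares on log-stabilized expression
#'
#' Fits the same linear model to every gene of a log-scale expression
#' matrix and extracts one coefficient of interest (a diagnosis
#' contrast, an age slope, ...). This is the package's deliberately
#' simple DE engine: OLS on log2(x + 1) values, with exact per-sample
#' Cook's distances retained for the outlier filter. Covariates (PMI,
#' sex, ApoE4, ...) enter as additional design columns of the same
#' fit, not as separate code paths.
#'
#' Genes with zero residual variance get SE 0, |t| = Inf and p = 0
#' (the noiseless limit); their Cook's distances are defined as 0.
#'
#' @param logm an `expr_matrix` with layer log2stab or centered (or a
#'   plain numeric matrix, e.g. negated delta-Ct values).
#' @param design a model formula over columns of `data`, e.g.
#'   `~ diagnosis` or `~ diagnosis + pmi`.
#' @param data a [sample_table()] (rows matching the columns of
#'   `logm` by `sample_id`).
#' @param coefficient name of the model-matrix column to report;
#'   defaults to the last column.
#' @return a data.frame of class `"de_fit"` with one row per gene:
#'   `gene`, `log2fc`, `se`, `t`, `p`, `padj` (BH), `cooks_max`,
#'   `cooks_pass` (NA until [cooks_filter()] is applied). Attributes:
#'   `cooks` (genes x samples matrix), `n_params`, `n_samples`, `df`,
#'   `coefficient`.
#' @export
fit_gene_linear_models <- function(logm, design, data,
                                   coefficient = NULL) {
  v <- unclass(logm)
  attr(v, "layer") <- NULL
  if (inherits(logm, "expr_matrix"))
    assert_layer(logm, c("log2stab", "centered"),
                 "fit_gene_linear_models")
  idx <- match(colnames(v), data$sample_id)
  if (anyNA(idx))
    stop("samples absent from metadata: ",
         paste(colnames(v)[is.na(idx)], collapse = ", "), call. = FALSE)
  data <- data[idx, , drop = FALSE]
  X <- stats::model.matrix(design, data = data)
  m <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (m < p + 2L)
    stop("need at least ", p + 2L, " samples for ", p, " parameters",
         call. = FALSE)
  if (is.null(coefficient)) coefficient <- colnames(X)[p]
  if (!coefficient %in% colnames(X))
    stop("coefficient '", coefficient, "' not in design columns: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)

  Y <- t(v)                                 # samples x genes
  coefs <- qr.coef(qrX, Y)                  # p x genes
  resid <- Y - X %*% coefs                  # samples x genes
  rss <- colSums(resid^2)
  # noiseless limit: residuals at rounding-error scale count as zero
  rss[rss <= .Machine$double.eps^0.75 * pmax(colSums(Y^2), 1)] <- 0
  df <- m - p
  s2 <- rss / df
  XtXinv <- matrix(NA_real_, p, p, dimnames = list(colnames(X),
                                                   colnames(X)))
  XtXinv[qrX$pivot, qrX$pivot] <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(s2 * XtXinv[coefficient, coefficient], 0))
  beta <- coefs[coefficient, ]
  tstat <- ifelse(se > 0, beta / se,
                  ifelse(beta == 0, 0, sign(beta) * Inf))
  pval <- 2 * stats::pt(-abs(tstat), df)
  h <- rowSums(qr.Q(qrX)^2)                 # leverages
  # Cook's D_gj = r_gj^2 h_j / (p s_g^2 (1 - h_j)^2); 0 when s_g = 0
  denom <- outer(h / (1 - h)^2 / p, s2, "/")
  cooks <- t(resid^2 * denom)
  cooks[s2 == 0, ] <- 0
  cooks[!is.finite(cooks)] <- Inf
  dimnames(cooks) <- list(rownames(v), rownames(X))

  out <- data.frame(gene = rownames(v), log2fc = beta, se = se,
                    t = tstat, p = pval, padj = bh_adjust(pval),
                    cooks_max = apply(cooks, 1L, max),
                    cooks_pass = NA, row.names = NULL)
  structure(out, cooks = cooks, n_params = p, n_samples = m, df = df,
            coefficient = coefficient,
            class = c("de_fit", "data.frame"))
}

#' Cook's-distance outlier filter
#'
#' Flags genes whose maximum per-sample Cook's distance exceeds the
#' upper-alpha critical value of the F(p, m - p) distribution (the
#' 1 - alpha quantile, alpha = 0.01 by default); such genes are
#' excluded from DE gene lists as likely driven by outlier samples.
#'
#' @param fit a `de_fit` from [fit_gene_linear_models()].
#' @param alpha upper-tail mass defining the critical value (default
#'   0.01, i.e. the 0.99 quantile).
#' @return the `de_fit` with `cooks_pass` set and a
#'   `cooks_critical` attribute.
#' @export
cooks_filter <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "de_fit"))
  p <- attr(fit, "n_params"); m <- attr(fit, "n_samples")
  if (m <= p) stop("no residual degrees of freedom", call. = FALSE)
  crit <- stats::qf(1 - alpha, p, m - p)
  fit$cooks_pass <- fit$cooks_max <= crit
  attr(fit, "cooks_critical") <- crit
  fit
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (monotone, bounded by 1) via
#' `stats::p.adjust(method = "BH")`, with input validation.
#'
#' @param pvals numeric vector of p values in [0, 1].
#' @return adjusted p values, same length and names.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Call DE genes from a filtered fit
#'
#' A gene is DE when its BH-adjusted p is at most `adj_p_max` and it
#' passed the Cook's filter; results are split by coefficient sign.
#'
#' @param fit a `de_fit` on which [cooks_filter()] has been applied.
#' @param adj_p_max adjusted-p threshold (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
call_de <- function(fit, adj_p_max = 0.05) {
  stopifnot(inherits(fit, "de_fit"))
  if (anyNA(fit$cooks_pass))
    stop("apply cooks_filter() before calling DE genes", call. = FALSE)
  hit <- fit$padj <= adj_p_max & fit$cooks_pass
  list(up = fit$gene[hit & fit$log2fc > 0],
       down = fit$gene[hit & fit$log2fc < 0])
}

#' Four-way concordance of two DE analyses
#'
#' Cross-tabulates shared genes by the sign of their effect in each
#' analysis (quadrant) and by which analyses called them significant
#' (adjusted p at or below the respective threshold, Cook's-passing
#' where filtered). Concordance is the fraction of genes significant
#' in either analysis whose effect signs agree.
#'
#' @param deA,deB `de_fit` objects.
#' @param sigA,sigB adjusted-p thresholds (default 0.05).
#' @return a list of class `"fourway_result"`: `genes` (per-gene
#'   data.frame with fcA, fcB, quadrant, sig_class), `class_counts`,
#'   `quadrant_counts`, `concordance`.
#' @export
fourway_concordance <- function(deA, deB, sigA = 0.05, sigB = 0.05) {
  shared <- intersect(deA$gene, deB$gene)
  if (length(shared) == 0L)
    stop("no shared genes between the two analyses", call. = FALSE)
  a <- deA[match(shared, deA$gene), ]
  b <- deB[match(shared, deB$gene), ]
  passA <- if (anyNA(a$cooks_pass)) TRUE else a$cooks_pass
  passB <- if (anyNA(b$cooks_pass)) TRUE else b$cooks_pass
  sA <- a$padj <= sigA & passA
  sB <- b$padj <= sigB & passB
  sig_class <- ifelse(sA & sB, "both",
                ifelse(sA, "A only", ifelse(sB, "B only", "neither")))
  quadrant <- paste(ifelse(a$log2fc >= 0, "up", "down"),
                    ifelse(b$log2fc >= 0, "up", "down"), sep = "/")
  either <- sA | sB
  concordance <- if (any(either))
    mean(sign(a$log2fc[either]) == sign(b$log2fc[either])) else NA_real_
  genes <- data.frame(gene = shared, fcA = a$log2fc, fcB = b$log2fc,
                      quadrant = quadrant, sig_class = sig_class,
                      row.names = NULL)
  structure(list(genes = genes,
                 class_counts = table(factor(sig_class,
                   levels = c("both", "A only", "B only", "neither"))),
                 quadrant_counts = table(quadrant),
                 concordance = concordance),
            class = "fourway_result")
}
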
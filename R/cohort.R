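#' 2x2 contingency table
#'
#' @param counts four nonnegative integers: a 2x2 matrix, or a vector
#'   `c(a, b, c, d)` filled column-wise (rows = status, columns =
#'   group).
#' @return an integer 2x2 matrix of class `"contingency_2x2"`.
#' @export
contingency_2x2 <- function(counts) {
  m <- matrix(as.numeric(counts), 2L, 2L)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(m) == 0)
    stop("table has no observations", call. = FALSE)
  structure(m, class = c("contingency_2x2", class(m)))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p value is the sum, over all tables with the observed margins,
#' of the hypergeometric point probabilities that do not exceed the
#' observed table's point probability (with relative tolerance 1e-7 on
#' the comparison — the convention of standard statistical
#' environments). A table with a zero margin carries no information
#' and returns p = 1 with a warning.
#'
#' @param tab a [contingency_2x2()] (or anything it accepts).
#' @return the two-sided p value.
#' @export
fisher_exact_two_sided <- function(tab) {
  m <- unclass(contingency_2x2(tab))
  r1 <- sum(m[1L, ]); c1 <- sum(m[, 1L]); n <- sum(m)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("zero margin; p = 1 by convention", call. = FALSE)
    return(1)
  }
  k <- max(0, r1 + c1 - n):min(r1, c1)    # support of the (1,1) cell
  logp <- stats::dhyper(k, c1, n - c1, r1, log = TRUE)
  obs <- stats::dhyper(m[1L, 1L], c1, n - c1, r1, log = TRUE)
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

#' Two-sample two-sided t test p value
#'
#' Student's pooled-variance test by default (the convention for
#' cohort tables), Welch optional. Two identical constant groups give
#' p = 1 (t = 0 by convention).
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param variant `"student"` or `"welch"`.
#' @return the two-sided p value.
#' @export
student_t_two_sample <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y, var.equal = (variant == "student"))$p.value
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics (type
#' 7, the default of mainstream statistical environments).
#'
#' @param x nonempty numeric vector.
#' @return named vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(x) {
  stopifnot(length(x) >= 1L)
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

#' Cohort characteristics table with per-variable tests
#'
#' Summarizes a metadata table by a binary group column: binary/logical
#' variables get count (percent) per group and a two-sided Fisher's
#' exact p; continuous variables get median (IQR) per group and a
#' Student's t p.
#'
#' @param meta a [sample_table()] (or compatible data.frame).
#' @param group_col binary grouping column (default "diagnosis").
#' @param binary_vars,continuous_vars variable names to summarize;
#'   defaults cover the usual cohort fields present in `meta`.
#' @param variant t-test variant for continuous variables.
#' @return a data.frame of class `"cohort_summary"`, one row per
#'   variable: group sizes, per-group summaries, test name, p value.
#' @export
build_cohort_table <- function(meta, group_col = "diagnosis",
                               binary_vars = intersect(
                                 c("sex", "apoe4"), names(meta)),
                               continuous_vars = intersect(
                                 c("age", "pmi", "mmse"), names(meta)),
                               variant = "student") {
  g <- meta[[group_col]]
  lev <- if (is.factor(g)) intersect(levels(g), unique(as.character(g)))
         else sort(unique(as.character(g)))
  if (length(lev) != 2L)
    stop("group column must be binary", call. = FALSE)
  gA <- as.character(g) == lev[1L]
  gB <- as.character(g) == lev[2L]
  rows <- list()
  for (v in binary_vars) {
    x <- meta[[v]]
    pos <- if (is.logical(x)) x else x == sort(unique(as.character(x)))[2L]
    tab <- contingency_2x2(c(sum(pos[gA]), sum(!pos[gA]),
                             sum(pos[gB]), sum(!pos[gB])))
    rows[[v]] <- data.frame(
      variable = v, test = "fisher",
      n_A = sum(gA), n_B = sum(gB),
      summary_A = sprintf("%d (%.0f%%)", sum(pos[gA]),
                          100 * mean(pos[gA])),
      summary_B = sprintf("%d (%.0f%%)", sum(pos[gB]),
                          100 * mean(pos[gB])),
      p = fisher_exact_two_sided(tab))
  }
  for (v in continuous_vars) {
    x <- meta[[v]]
    mA <- median_iqr(x[gA]); mB <- median_iqr(x[gB])
    rows[[v]] <- data.frame(
      variable = v, test = paste0(variant, "_t"),
      n_A = sum(gA), n_B = sum(gB),
      summary_A = sprintf("%.3g (%.3g-%.3g)", mA[1L], mA[2L], mA[3L]),
      summary_B = sprintf("%.3g (%.3g-%.3g)", mB[1L], mB[2L], mB[3L]),
      p = student_t_two_sample(x[gA], x[gB], variant))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, groups = lev,
            class = c("cohort_summary", "data.frame"))
}
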
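test_that("median-of-ratios size factors satisfy the defining identities", {
  # identical columns -> all 1
  m <- toy_expr(matrix(rep(c(5L, 10L, 20L), 3), nrow = 3))
  expect_equal(unname(size_factors_median_of_ratios(m)), rep(1, 3))

  # sample2 = 2 x sample1 -> factors (1/sqrt(2), sqrt(2))
  m2 <- toy_expr(cbind(c(4L, 8L, 16L), c(8L, 16L, 32L)))
  sf <- size_factors_median_of_ratios(m2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  # scale-equivariance in the 2-sample case: scaling sample 2 by c
  # multiplies its factor by sqrt(c) and divides the other by sqrt(c)
  set.seed(1)
  base <- matrix(rpois(20, 50) + 1L, nrow = 10)
  for (cc in c(2, 5)) {
    m3 <- toy_expr(base)
    m4 <- toy_expr(cbind(base[, 1], base[, 2] * cc))
    f3 <- size_factors_median_of_ratios(m3)
    f4 <- size_factors_median_of_ratios(m4)
    expect_equal(unname(f4[2] / f3[2]), sqrt(cc), tolerance = 1e-10)
    expect_equal(unname(f4[1] / f3[1]), 1 / sqrt(cc), tolerance = 1e-10)
  }

  expect_error(size_factors_median_of_ratios(
    toy_expr(matrix(c(0L, 1L, 1L, 0L), 2))), "no gene")
})

test_that("size factors match a brute-force definition and DESeq2", {
  brute <- function(m) {
    ref <- apply(m, 1, function(r) if (any(r == 0)) NA
                 else exp(mean(log(r))))
    apply(m, 2, function(col)
      median((col / ref)[!is.na(ref)]))
  }
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rpois(20, 30), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    expect_equal(unname(size_factors_median_of_ratios(m)),
                 unname(brute(m)), tolerance = 1e-12)
  }
  skip_if_not_installed("DESeq2")
  set.seed(8)
  m <- matrix(rpois(60, 100) + 1L, nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(unname(size_factors_median_of_ratios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("nRPKM follows its per-kb per-million definition", {
  m <- toy_expr(matrix(10L, 1, 1), genes = "g1")
  # pad library to 1e6 total with a second gene
  m <- toy_expr(rbind(c(10L), c(1e6L - 10L)),
                genes = c("g1", "filler"))
  len <- c(g1 = 1000, filler = 1000)
  out <- compute_nrpkm(m, len)
  expect_equal(unclass(out)["g1", 1], 10, tolerance = 1e-12)
  # doubling the gene length halves its nRPKM
  len2 <- c(g1 = 2000, filler = 1000)
  expect_equal(unclass(compute_nrpkm(m, len2))["g1", 1], 5,
               tolerance = 1e-12)
  # identical samples give identical columns; missing length drops gene
  m2 <- toy_expr(cbind(c(4L, 100L), c(4L, 100L)),
                 genes = c("g1", "g2"))
  out2 <- compute_nrpkm(m2, c(g1 = 500, g2 = 1500))
  expect_equal(unclass(out2)[, 1], unclass(out2)[, 2])
  expect_warning(out3 <- compute_nrpkm(m2, c(g1 = 500)), "dropped")
  expect_equal(rownames(out3), "g1")
  expect_identical(expr_layer(out2), "nrpkm")
})

test_that("log stabilization is log2(x + 1), monotone, zero-preserving", {
  m <- toy_expr(matrix(c(0L, 1L, 7L, 3L), 2))
  out <- log_stabilize(m)
  expect_equal(unclass(out)[, 1], c(g1 = 0, g2 = 1))
  expect_equal(unclass(out)["g1", 2], 3)
  expect_identical(expr_layer(out), "log2stab")
  set.seed(2)
  x <- sort(runif(50, 0, 100))
  lx <- unclass(log_stabilize(toy_expr(matrix(x, 50, 1,
    dimnames = list(paste0("g", 1:50), "s1")), "nrpkm")))
  expect_true(all(diff(lx[, 1]) >= 0))
})

test_that("total-transcript normalization rescales cells exactly", {
  counts <- matrix(c(2L, 3L, 5L, 1L, 1L, 0L), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  cells <- toy_cells(counts)
  out <- total_transcript_normalize(cells, target_total = 10)
  expect_equal(as.numeric(out$counts[, "c1"]), c(2, 3, 5))
  expect_equal(as.numeric(out$counts[, "c2"]), c(5, 5, 0))
  expect_equal(unname(Matrix::colSums(out$counts)), c(10, 10),
               tolerance = 1e-9)
  # proportions preserved
  expect_equal(as.numeric(out$counts[, "c1"] / sum(out$counts[, "c1"])),
               counts[, "c1"] / sum(counts[, "c1"]),
               ignore_attr = TRUE)
  zero <- toy_cells(matrix(c(1L, 0L), 1, 2,
                           dimnames = list("g1", c("c1", "c2"))))
  expect_error(total_transcript_normalize(zero), "zero-count")
})

test_that("row Z scores use the sample (n-1) standard deviation", {
  m <- toy_expr(matrix(c(1L, 2L, 3L), 1), genes = "g1")
  z <- zscore_rows(m)
  expect_equal(unname(unclass(z)[1, ]), c(-1, 0, 1))
  # population-sd convention would give +-1.2247; assert we differ
  expect_false(isTRUE(all.equal(unname(unclass(z)[1, 1]), -1.2247,
                                tolerance = 1e-3)))
  m2 <- toy_expr(matrix(c(5L, 5L, 5L, 1L, 2L, 9L), 2, byrow = TRUE))
  expect_warning(z2 <- zscore_rows(m2), "zero-variance")
  expect_equal(unname(unclass(z2)[1, ]), c(0, 0, 0))
  expect_equal(unname(rowMeans(unclass(z2))), c(0, 0))
  expect_error(zscore_rows(toy_expr(matrix(1L, 2, 1))), ">= 2 samples")
})

test_that("IQR-based variable gene selection ranks and tie-breaks", {
  v <- rbind(c(0, 5, 10, 15),    # IQR 7.5
             c(0, 1, 2, 3),      # IQR 1.5
             c(0, 3, 6, 9))      # IQR 4.5
  m <- toy_expr(v, layer = "nrpkm", genes = c("gB", "gC", "gA"))
  expect_equal(top_variable_genes_iqr(m, 2), c("gB", "gA"))
  # all-constant: lexicographic tie-break
  m2 <- toy_expr(matrix(1, 3, 3), layer = "nrpkm",
                 genes = c("gC", "gA", "gB"))
  expect_equal(top_variable_genes_iqr(m2, 2), c("gA", "gB"))
  # invariant to sample order
  perm <- toy_expr(v[, c(3, 1, 4, 2)], layer = "nrpkm",
                   genes = c("gB", "gC", "gA"))
  expect_equal(top_variable_genes_iqr(perm, 3),
               top_variable_genes_iqr(m, 3))
  expect_error(top_variable_genes_iqr(m, 0), "positive")
})
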
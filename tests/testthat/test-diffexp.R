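fit_toy <- function(values, samples, design = ~ diagnosis, ...) {
  m <- expression_matrix(values, "log2stab")
  fit_gene_linear_models(m, design, samples, ...)
}

test_that("per-gene OLS recovers noiseless and near-noiseless effects", {
  samples <- toy_samples(3, 3)
  v <- matrix(c(0, 0, 0, 1, 1, 1), nrow = 1,
              dimnames = list("g1", samples$sample_id))
  set.seed(1)
  v <- rbind(v, g2 = v[1, ] + rnorm(6, 0, 1e-6))
  fit <- fit_toy(v, samples)
  expect_equal(fit$log2fc, c(1, 1), tolerance = 1e-4)
  expect_equal(fit$p[1], 0)          # zero-residual noiseless limit
  expect_true(is.infinite(fit$t[1]))
  expect_lt(fit$p[2], 1e-6)

  # continuous design: values exactly linear in age
  meta <- toy_samples(4, 4)
  meta$age <- c(60, 65, 70, 75, 80, 85, 90, 95)
  va <- matrix(0.1 * meta$age + 2, nrow = 1,
               dimnames = list("g1", meta$sample_id))
  fa <- fit_toy(va, meta, design = ~ age, coefficient = "age")
  expect_equal(fa$log2fc, 0.1, tolerance = 1e-12)
  expect_equal(fa$p, 0)

  # permuting sample order changes nothing
  set.seed(2)
  vb <- matrix(rnorm(16), 2, dimnames = list(c("g1", "g2"),
                                             meta$sample_id))
  perm <- sample(8)
  f1 <- fit_toy(vb, meta)
  f2 <- fit_toy(vb[, perm], meta)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
  expect_equal(f1$log2fc, f2$log2fc, tolerance = 1e-12)

  # rank-deficient designs are refused with the offending column named
  meta$dup <- as.integer(meta$diagnosis == "AD")
  expect_error(fit_toy(vb, meta, design = ~ diagnosis + dup), "dup")
})

test_that("analytic Cook's distances match the leave-one-out refit oracle", {
  loo_cooks <- function(y, X) {
    fit <- stats::lm.fit(X, y)
    p <- ncol(X)
    s2 <- sum(fit$residuals^2) / (length(y) - p)
    beta <- fit$coefficients
    vapply(seq_along(y), function(j) {
      fit_j <- stats::lm.fit(X[-j, , drop = FALSE], y[-j])
      d <- beta - fit_j$coefficients
      as.numeric(t(d) %*% crossprod(X) %*% d) / (p * s2)
    }, numeric(1))
  }
  set.seed(3)
  for (rep in 1:5) {
    n <- 10
    meta <- toy_samples(5, 5)
    meta$age <- round(rnorm(n, 75, 8))
    X <- stats::model.matrix(~ diagnosis + age, meta)
    y <- rnorm(n)
    v <- matrix(y, 1, dimnames = list("g1", meta$sample_id))
    fit <- fit_toy(v, meta, design = ~ diagnosis + age)
    expect_equal(unname(attr(fit, "cooks")[1, ]),
                 unname(loo_cooks(y, X)), tolerance = 1e-8)
  }
})

test_that("Cook's filter removes outlier-driven genes, never adds any", {
  # a single outlier's Cook's distance saturates at df / (p (g - 1))
  # for a group of size g, so only a small group can push it past the
  # F critical value: use 3 controls vs 37 AD with the outlier among
  # the controls
  samples <- toy_samples(3, 37)
  set.seed(4)
  clean <- matrix(rnorm(80, mean = 5, sd = 0.1), 2,
                  dimnames = list(c("g1", "g2"), samples$sample_id))
  outl <- clean
  outl["g2", 1] <- 50                     # one sample at 10x log value
  fit <- cooks_filter(fit_toy(outl, samples))
  expect_true(fit$cooks_pass[fit$gene == "g1"])
  expect_false(fit$cooks_pass[fit$gene == "g2"])
  # zero-residual gene has all-zero distances and passes
  flat <- matrix(rep(c(1, 2), c(3, 37)), 1, byrow = TRUE,
                 dimnames = list("g1", samples$sample_id))
  ffit <- cooks_filter(fit_toy(flat, samples))
  expect_equal(ffit$cooks_max, 0)
  expect_true(ffit$cooks_pass)
  # filtered list is a subset of the unfiltered list
  called <- call_de(fit, adj_p_max = 1)
  expect_true(all(c(called$up, called$down) %in% fit$gene))
  expect_false("g2" %in% c(called$up, called$down))
})

test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in input ranks, bounded by 1
  set.seed(5)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("planted DE genes are recovered at controlled FDR", {
  up <- sprintf("g%04d", 301:330); down <- sprintf("g%04d", 331:340)
  effects <- setNames(c(rep(1, 30), rep(-1, 10)), c(up, down))
  recov <- sapply(1:10, function(seed) {
    cfg <- sim_config(seed = seed, planted_effects = effects)
    sim <- simulate_sorted_counts(cfg)
    fit <- cooks_filter(fit_gene_linear_models(
      log_stabilize(sim$counts), ~ diagnosis, sim$samples))
    called <- call_de(fit, adj_p_max = 0.05)
    hits <- c(called$up, called$down)
    c(sens = (sum(up %in% called$up) + sum(down %in% called$down)) / 40,
      fdr = if (length(hits)) mean(!hits %in% names(effects)) else 0)
  })
  expect_gte(mean(recov["sens", ]), 0.8)
  expect_lte(mean(recov["fdr", ]), 0.1)
  # threshold 1.0 calls every cooks-passing gene
  cfg <- sim_config(seed = 1)
  sim <- simulate_sorted_counts(cfg)
  fit <- cooks_filter(fit_gene_linear_models(
    log_stabilize(sim$counts), ~ diagnosis, sim$samples))
  all_called <- call_de(fit, adj_p_max = 1)
  expect_equal(sort(c(all_called$up, all_called$down)),
               sort(fit$gene[fit$cooks_pass & fit$log2fc != 0]))
})

test_that("four-way concordance classifies genes by sign and significance", {
  samples <- toy_samples(5, 5)
  set.seed(6)
  v <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4),
                                            samples$sample_id))
  fit <- cooks_filter(fit_toy(v, samples))
  self <- fourway_concordance(fit, fit)
  expect_equal(self$concordance,
               if (any(fit$padj <= 0.05)) 1 else NA_real_)
  expect_true(all(self$genes$fcA == self$genes$fcB))
  neg <- fit; neg$log2fc <- -fit$log2fc
  anti <- fourway_concordance(fit, neg)
  if (!is.na(anti$concordance)) expect_equal(anti$concordance, 0)

  # exhaustive small case with hand-set stats
  mk_fit <- function(fc, padj) {
    structure(data.frame(gene = paste0("g", seq_along(fc)),
                         log2fc = fc, se = 1, t = fc, p = padj,
                         padj = padj, cooks_max = 0, cooks_pass = TRUE),
              class = c("de_fit", "data.frame"))
  }
  a <- mk_fit(c(2, -1, 1, -2), c(0.01, 0.01, 0.5, 0.5))
  b <- mk_fit(c(1, 1, -1, -1), c(0.01, 0.5, 0.01, 0.5))
  fw <- fourway_concordance(a, b)
  expect_equal(as.numeric(fw$class_counts[c("both", "A only",
                                            "B only", "neither")]),
               c(1, 1, 1, 1))
  expect_equal(unname(fw$quadrant_counts[c("up/up", "down/up",
                                           "up/down", "down/down")]),
               c(1, 1, 1, 1), ignore_attr = TRUE)
  # genes significant in either: g1 (concordant), g2, g3 -> 1/3
  expect_equal(fw$concordance, 1 / 3)
  expect_error(fourway_concordance(a, mk_fit(1, 1)[0, ]), "shared")
})
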
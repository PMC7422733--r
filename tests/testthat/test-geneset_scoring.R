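test_that("control centering zeroes the control mean and is idempotent", {
  set.seed(4)
  m <- toy_expr(matrix(rpois(40, 30), nrow = 5))
  logm <- log_stabilize(m)
  ctrl <- c("s1", "s2", "s3")
  cen <- control_center(logm, ctrl)
  expect_equal(unname(rowMeans(unclass(cen)[, ctrl])), rep(0, 5),
               tolerance = 1e-12)
  twice <- control_center(cen, ctrl)
  expect_equal(unclass(twice), unclass(cen), ignore_attr = TRUE)
  # hand example: control values (1,3), AD value 4 -> centered AD 2
  v <- matrix(2^c(1, 3, 4) - 1, 1,
              dimnames = list("g1", c("c1", "c2", "a1")))
  cen2 <- control_center(expression_matrix(log2(v + 1), "log2stab"),
                         c("c1", "c2"))
  expect_equal(unclass(cen2)["g1", "a1"], 2)
  expect_error(control_center(logm, character(0)), "empty")
  expect_error(control_center(logm, "nope"), "absent")
})

test_that("gene set scores average centered values over present members", {
  cen <- toy_centered(matrix(c(1, 2, 6, 9), ncol = 1),
                      genes = c("g1", "g2", "g3", "g4"))
  s <- gene_set("three", c("g1", "g2", "g3"))
  st <- gene_set_score(cen, s)
  expect_equal(st$score, 3)
  expect_equal(attr(st, "n_genes_used"), 3L)
  # singleton set equals the gene's value; all-zero matrix scores 0
  expect_equal(gene_set_score(cen, gene_set("one", "g4"))$score, 9)
  zero <- toy_centered(matrix(0, 3, 2))
  expect_equal(gene_set_score(zero, gene_set("z", c("g1", "g3")))$score,
               c(0, 0))
  # absent members are dropped, not imputed
  suppressMessages(
    st2 <- gene_set_score(cen, gene_set("partial",
                                        c("g1", "g2", "absent"))))
  expect_equal(st2$score, 1.5)
  expect_equal(attr(st2, "n_genes_used"), 2L)
  expect_error(gene_set_score(cen, gene_set("none", "nope")),
               "no member.*none")
})

test_that("DE scores apply direction weights and reduce to plain scores", {
  cen <- toy_centered(matrix(c(2, -4, -1), ncol = 1),
                      genes = c("g1", "g2", "g3"))
  signed <- gene_set("sig", c("g1", "g2"), c(1, -1))
  expect_equal(de_score(cen, signed)$score, 3)        # (2 + 4)/2
  expect_equal(de_score(cen, gene_set("down1", "g3", -1))$score, 1)
  set.seed(5)
  cen2 <- toy_centered(matrix(rnorm(30), 5))
  plain <- gene_set("p", paste0("g", 1:4))
  expect_equal(de_score(cen2, plain)$score,
               gene_set_score(cen2, plain)$score)
})

test_that("shared-gene restriction and exclusion edit sets correctly", {
  s <- gene_set("s", c("g1", "g2", "g3"), c(1, -1, 1))
  d1 <- toy_centered(matrix(0, 3, 2), genes = c("g1", "g2", "g3"))
  d2 <- toy_centered(matrix(0, 2, 2), genes = c("g2", "g3"))
  r <- restrict_to_shared_genes(list(s), list(d1))[[1L]]
  expect_equal(r$members, s$members)
  r2 <- restrict_to_shared_genes(list(s), list(d1, d2))[[1L]]
  expect_equal(r2$members, c("g2", "g3"))
  expect_equal(unname(r2$direction), c(-1, 1))
  r3 <- restrict_to_shared_genes(list(s), list(d2, d1))[[1L]]
  expect_identical(r2$members, r3$members)  # dataset order irrelevant

  e <- exclude_genes(s, "APOE")
  expect_equal(e$members, s$members)        # disjoint exclusion
  with_apoe <- gene_set("a", c("APOE", "g1"))
  expect_equal(length(exclude_genes(with_apoe, "APOE")$members), 1L)
  expect_warning(exclude_genes(s, s$members), "emptied")
})

test_that("group comparisons are antisymmetric and calibrated", {
  st <- toy_centered(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), nrow = 1) +
                       matrix(rnorm(8, 0, 1e-6), 1))
  sc <- gene_set_score(st, gene_set("g", "g1"))
  grp <- toy_samples(4, 4, prefix = "s0")[1:8, ]
  grp$sample_id <- paste0("s", 1:8)
  cmp <- compare_groups(sc, grp)
  expect_equal(cmp$delta, 1, tolerance = 1e-4)
  expect_lt(cmp$p_value, 1e-6)
  # swapped labels negate delta, keep p
  grp2 <- grp
  grp2$diagnosis <- factor(rev(as.character(grp$diagnosis)),
                           levels = c("control", "AD"))
  cmp2 <- compare_groups(sc, grp2)
  expect_equal(cmp2$delta, -cmp$delta)
  expect_equal(cmp2$p_value, cmp$p_value)
  # identical multisets: delta 0; degenerate constant groups: p 1
  same <- new_score <- sc
  same$score <- rep(c(2, 3), 4)
  expect_equal(compare_groups(same, grp)$delta, 0)
  const <- sc; const$score <- rep(1, 8)
  expect_equal(compare_groups(const, grp)$p_value, 1)
  # welch equals student for equal sizes and exactly equal variances
  sc3 <- sc; sc3$score <- c(1, 2, 3, 4, 3, 4, 5, 6)
  expect_equal(compare_groups(sc3, grp, variant = "welch")$p_value,
               compare_groups(sc3, grp, variant = "student")$p_value,
               tolerance = 1e-12)
})

test_that("stratification partitions scores without re-centering", {
  set.seed(8)
  cen <- toy_centered(matrix(rnorm(12), 2))
  sc <- gene_set_score(cen, gene_set("g", c("g1", "g2")))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     braak_group = c("low", "high", "low", "high",
                                     "low", "low"))
  out <- stratify_scores(sc, meta, "braak_group", c("low", "high"))
  expect_named(out, c("low", "high"))
  expect_equal(nrow(out$low) + nrow(out$high), 6L)
  expect_equal(out$high$score,
               sc$score[sc$sample_id %in% c("s2", "s4")])
  expect_warning(
    stratify_scores(sc, meta, "braak_group",
                    c("low", "high", "mid")), "no samples")
  expect_error(stratify_scores(sc, meta, "braak_group", "low"),
               "unknown level")
  one <- stratify_scores(sc[sc$sample_id == "s1", ], meta,
                         "braak_group", c("low"))
  expect_equal(nrow(one$low), 1L)
})

test_that("balancing discards minimally and deterministically", {
  # two bins: one perfectly mixed, one AD-only -> AD-only bin dropped,
  # mixed bin untouched (enumerated optimum: nothing to discard)
  scores <- new_score_table_for_test(
    c(sprintf("a%d", 1:8), sprintf("c%d", 1:4)),
    c(1, 1, 1, 1, 9, 9, 9, 9, 1, 1, 1, 1))
  meta <- sample_table(data.frame(
    sample_id = c(sprintf("a%d", 1:8), sprintf("c%d", 1:4)),
    diagnosis = rep(c("AD", "control"), c(8, 4))))
  plan <- myeloid_balance(scores, meta, n_bins = 2, seed = 1)
  expect_setequal(plan$discarded_sample_ids, sprintf("a%d", 5:8))
  expect_setequal(plan$kept_sample_ids,
                  c(sprintf("a%d", 1:4), sprintf("c%d", 1:4)))
  expect_equal(plan$target_fraction, 0.5)

  # same seed -> identical plan; any seed -> same per-bin kept counts
  set.seed(99)
  sc2 <- new_score_table_for_test(
    sprintf("s%02d", 1:40), c(sort(rnorm(20)), sort(rnorm(20)) + 0.5))
  meta2 <- sample_table(data.frame(
    sample_id = sprintf("s%02d", 1:40),
    diagnosis = rep(c("control", "AD"), each = 20)))
  p1 <- myeloid_balance(sc2, meta2, n_bins = 5, seed = 7)
  p2 <- myeloid_balance(sc2, meta2, n_bins = 5, seed = 7)
  expect_identical(p1$assignments, p2$assignments)
  p3 <- myeloid_balance(sc2, meta2, n_bins = 5, seed = 8)
  counts_by_bin <- function(p) {
    k <- p$assignments[p$assignments$kept, ]
    table(k$bin, k$diagnosis)
  }
  expect_equal(counts_by_bin(p1), counts_by_bin(p3))
  # balancing never adds samples, and partitions the input
  expect_setequal(c(p1$kept_sample_ids, p1$discarded_sample_ids),
                  sc2$sample_id)
  expect_error(myeloid_balance(sc2, meta2, n_bins = 0, seed = 1),
               "n_bins")
})

test_that("per-bin kept fractions are as close to target as achievable", {
  # enumeration oracle: for each mixed bin, the best reachable AD
  # fraction by discarding from one group only
  set.seed(12)
  for (rep in 1:5) {
    n <- 30
    sc <- new_score_table_for_test(sprintf("s%02d", 1:n), rnorm(n))
    meta <- sample_table(data.frame(
      sample_id = sprintf("s%02d", 1:n),
      diagnosis = sample(rep(c("control", "AD"), c(12, 18)))))
    plan <- myeloid_balance(sc, meta, n_bins = 4, seed = rep)
    f <- plan$target_fraction
    asg <- plan$assignments
    for (b in unique(asg$bin)) {
      all_b <- asg[asg$bin == b, ]
      a <- sum(all_b$diagnosis == "AD")
      c_ <- sum(all_b$diagnosis == "control")
      if (a == 0 || c_ == 0) {
        expect_false(any(all_b$kept))
        next
      }
      kept_b <- all_b[all_b$kept, ]
      got <- mean(kept_b$diagnosis == "AD")
      best <- min(abs(c(sapply(1:a, function(k) k / (k + c_)),
                        sapply(1:c_, function(k) a / (a + k))) - f))
      expect_equal(abs(got - f), best, tolerance = 1e-12)
    }
  }
})
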
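test_that("pooled t-test matches the closed form and t.test", {
  qt <- two_group_qt(c(1, 2, 3), c(4, 5, 6))
  d <- feature_ttest(qt, two_group_contrast)
  expect_equal(d$log2fc, 3)
  expect_equal(d$stat, -3 / sqrt(2 / 3), tolerance = 1e-12) # -3.6742
  expect_equal(d$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12) # 0.02131
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(d$stat, unname(ref$statistic))
  expect_equal(d$p, ref$p.value)
  expect_equal(d$s, sign(3) * -log10(d$p))
})

test_that("identical groups give t = 0, p = 1, s = 0", {
  qt <- two_group_qt(c(1, 2, 3), c(1, 2, 3))
  d <- feature_ttest(qt, two_group_contrast)
  expect_equal(d$stat, 0)
  expect_equal(d$p, 1)
  expect_equal(d$s, 0)
})

test_that("Welch variant matches t.test(var.equal = FALSE)", {
  set.seed(1)
  a <- rnorm(4, sd = 1)
  b <- rnorm(5, sd = 3)
  qt <- two_group_qt(a, b)
  d <- feature_ttest(qt, two_group_contrast, var_equal = FALSE)
  ref <- t.test(a, b)
  expect_equal(d$stat, unname(ref$statistic))
  expect_equal(d$p, ref$p.value)
})

test_that("zero-variance features get the p sentinel and a flag, never dropped", {
  qt <- two_group_qt(c(1, 1, 1), c(2, 2, 2))
  d <- feature_ttest(qt, two_group_contrast)
  expect_equal(d$p, 1e-300)
  expect_equal(d$flag, "zero_variance")
  expect_equal(d$s, 300) # capped signed score, upregulated

  # a feature with <2 present replicates is flagged, not removed
  qt2 <- two_group_qt(c(1, 2, 3), c(4, 5, 6), n_features = 2)
  qt2$values[2, 2:3] <- NA
  d2 <- feature_ttest(qt2, two_group_contrast)
  expect_equal(nrow(d2), 2)
  expect_equal(d2$flag[2], "insufficient_replicates")
  expect_true(is.na(d2$p[2]))
})

test_that("BH adjustment matches the literal step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(3:200, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("one-way ANOVA matches the closed form and aov", {
  vals <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), nrow = 1)
  qt <- matrix_qt(vals)
  labels <- rep(c("g1", "g2", "g3"), each = 3)
  d <- feature_anova(qt, labels)
  expect_equal(d$stat, 3)
  expect_equal(d$p, 0.125) # survival of F(2,6): (1 + F/3)^-3 at F=3
  expect_true("log2fc_g3_vs_g1" %in% names(d))
  expect_equal(d$log2fc_g3_vs_g1, 2)
  expect_equal(d$log2fc, 2) # largest-magnitude pair difference

  # all groups identical
  d0 <- feature_anova(matrix_qt(matrix(rep(c(1, 2, 3), 3), nrow = 1)), labels)
  expect_equal(d0$stat, 0)
  expect_equal(d0$p, 1)

  set.seed(11)
  vals <- matrix(rnorm(5 * 9), nrow = 5)
  dr <- feature_anova(matrix_qt(vals), labels)
  for (i in 1:5) {
    fit <- summary(aov(vals[i, ] ~ factor(labels)))[[1]]
    expect_equal(dr$stat[i], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(dr$p[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_error(feature_anova(matrix_qt(vals), rep(c("g1", "g2"), c(4, 5))), ">=3")
})

test_that("threshold filter reproduces the documented survivor set", {
  d <- mock_diff(
    paste0("f", 1:6),
    log2fc = log2(c(2.5, 1.5, 4.0, 2.0, 8.0, 1.1)),
    q = c(0.1, 0.1, 0.3, 0.15, 0.19, 0.5)
  )
  out <- apply_filter(d, filter_spec(0.2, 2))
  expect_identical(out$feature_id, c("f1", "f4", "f5"))
  expect_equal(attr(out, "n_survivors"), 3)

  all_pass <- apply_filter(d, filter_spec(1, 1))
  expect_equal(nrow(all_pass), 6)
  empty <- apply_filter(d[0, ], filter_spec(0.2, 2))
  expect_equal(nrow(empty), 0)
  expect_error(apply_filter(d, filter_spec(0.05, 3, test = "anova")), "anova")
})

test_that("filter survivor counts are monotone in both thresholds", {
  set.seed(3)
  d <- mock_diff(paste0("f", 1:200), log2fc = rnorm(200), q = runif(200))
  folds <- c(1, 1.5, 2, 3, 5)
  qs <- c(0.01, 0.05, 0.1, 0.3, 1)
  by_fold <- sapply(folds, function(f) attr(apply_filter(d, filter_spec(0.2, f)), "n_survivors"))
  by_q <- sapply(qs, function(q) attr(apply_filter(d, filter_spec(q, 2)), "n_survivors"))
  expect_true(all(diff(by_fold) <= 0))
  expect_true(all(diff(by_q) >= 0))
})

test_that("median centering behaves and is idempotent", {
  qt <- matrix_qt(matrix(c(1, 5, 2, 6, 3, 7), nrow = 2, byrow = FALSE))
  out <- normalize_median_center(qt)
  expect_equal(unname(out$values[, 1]), c(-2, 2))
  again <- normalize_median_center(out)
  expect_equal(again$values, out$values)
  set.seed(2)
  qt2 <- matrix_qt(matrix(rnorm(50), nrow = 10))
  out2 <- normalize_median_center(qt2)
  expect_true(all(abs(apply(out2$values, 2, median)) < 1e-12))
  qt3 <- matrix_qt(matrix(c(1, NA, NA, 2, 2, 3), nrow = 3))
  expect_error(normalize_median_center(qt3), "<2 present")
})

test_that("protein summarization is the median of mean-centered peptides", {
  vals <- rbind(c(1, 2, 3, 4), c(0, 0, 4, 4))
  qt <- matrix_qt(vals)
  qt$features$protein_id <- c("P1", "P1")
  out <- protein_summarize(qt)
  expect_equal(unname(out$values[1, ]), c(-1.75, -1.25, 1.25, 1.75))

  single <- matrix_qt(matrix(c(2, 4), nrow = 1))
  expect_equal(unname(protein_summarize(single)$values[1, ]), c(-1, 1))

  # duplicating every peptide leaves the summary unchanged
  dup <- matrix_qt(rbind(vals, vals))
  dup$features$protein_id <- rep("P1", 4)
  expect_equal(protein_summarize(dup)$values, out$values)

  # per-peptide constant offsets are removed by the centering
  shifted <- matrix_qt(vals + c(10, -3))
  shifted$features$protein_id <- c("P1", "P1")
  expect_equal(protein_summarize(shifted)$values, out$values)
})

test_that("protein collapse keeps the largest-magnitude site with tie rules", {
  sc <- tibble::tibble(
    protein_id = c("P1", "P1", "P2", "P3", "P3"),
    feature_id = c("P1_a", "P1_b", "P2_a", "P3_a", "P3_b"),
    score = c(5, -6, 2, 4, -4)
  )
  out <- collapse_to_protein(sc)
  expect_equal(out$score[out$protein_id == "P1"], -6)
  expect_equal(out$feature_id[out$protein_id == "P1"], "P1_b")
  expect_equal(out$score[out$protein_id == "P2"], 2)
  expect_equal(out$score[out$protein_id == "P3"], 4) # positive preferred on tie
  expect_true(out$tie[out$protein_id == "P3"])
  expect_false(out$tie[out$protein_id == "P1"])
  expect_error(collapse_to_protein(sc[0, ]), "no scored")
})

test_that("signed-t ordering agrees with a brute-force sort", {
  d <- mock_diff(c("f1", "f2", "f3"), log2fc = c(1, -1, 1), stat = c(-3, 2, -1))
  rl <- signed_t_order(d)
  expect_identical(rl$id, c("f1", "f3", "f2"))

  set.seed(5)
  dr <- mock_diff(paste0("f", 1:1000), log2fc = rnorm(1000), stat = rnorm(1000))
  rl2 <- signed_t_order(dr)
  sc <- sign(dr$log2fc) * abs(dr$stat)
  expect_identical(rl2$id, dr$feature_id[order(-sc, dr$feature_id, method = "radix")])
})

test_that("summed fold-change signature is additive and order-correct", {
  dA <- mock_diff(c("f1", "f2", "f3"), log2fc = c(1, -1, 3))
  dB <- mock_diff(c("f1", "f2", "f3"), log2fc = c(2, 0.5, -3))
  rl <- sum_fold_change_signature(list(dA, dB))
  expect_identical(rl$id, c("f1", "f3", "f2"))
  expect_equal(rl$score, c(3, 0, -0.5))

  solo <- sum_fold_change_signature(list(dA))
  expect_identical(solo$id, rank_features(setNames(dA$log2fc, dA$feature_id))$id)

  dbl <- sum_fold_change_signature(list(dA, dA))
  expect_equal(dbl$score, 2 * solo$score)
  expect_identical(dbl$id, solo$id)
})
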
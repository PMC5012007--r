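top_heavy_list <- function(N = 20) {
  rank_features(setNames(seq(N, 1), sprintf("g%03d", seq_len(N))))
}

test_that("KS statistic and permutation p behave on the canonical fixtures", {
  rl <- top_heavy_list(20)
  hit <- ks_permutation_test(rl, sprintf("g%03d", 1:5), B = 10000, seed = 1)
  expect_equal(hit$stat, 0.75) # 5/5 - 5/20
  expect_lte(hit$p, 0.01)
  expect_identical(hit$leading_edge[[1]], sprintf("g%03d", 1:5))

  spread <- ks_permutation_test(rl, sprintf("g%03d", c(4, 8, 12, 16, 20)),
    B = 10000, seed = 1
  )
  expect_lt(spread$stat, 0.2)
  expect_gt(spread$p, 0.5)

  full <- ks_permutation_test(rl, rl$id, B = 199, seed = 1)
  expect_equal(full$stat, 0)
  expect_equal(full$p, 1)
  expect_equal(full$flag, "set_equals_universe")

  expect_error(ks_permutation_test(rl, c("zz1", "zz2"), B = 199), "intersect")
  expect_error(ks_permutation_test(rl, "g001", B = 50), "B must be")
})

test_that("KS D matches the direct ECDF oracle on random sets", {
  set.seed(9)
  rl <- top_heavy_list(200)
  for (i in 1:20) {
    m <- sample(3:40, 1)
    members <- sample(rl$id, m)
    D <- ks_permutation_test(rl, members, B = 99, seed = 1)$stat
    expect_equal(D, ks_D_oracle(sort(match(members, rl$id)), m, 200), tolerance = 1e-12)
  }
})

test_that("permutation p respects the add-one floor and seed determinism", {
  rl <- top_heavy_list(50)
  r1 <- ks_permutation_test(rl, rl$id[1:10], B = 199, seed = 3)
  r2 <- ks_permutation_test(rl, rl$id[1:10], B = 199, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 200)
})

test_that("unweighted running-sum ES is the rescaled KS D", {
  set.seed(13)
  for (i in 1:50) {
    N <- sample(30:120, 1)
    m <- sample(3:12, 1)
    rl <- rank_features(setNames(rnorm(N), sprintf("id%04d", seq_len(N))))
    members <- sample(rl$id, m)
    g <- gsea_es_nes(rl, list(s = members), B = 99, seed = 1, weight = 0)
    D <- ks_permutation_test(rl, members, B = 99, seed = 1)$stat
    # the max positive running-sum deviation equals D * N / (N - m);
    # gsea reports the two-sided extremum, so compare only when positive
    if (g$stat > 0) {
      expect_equal(g$stat, D * N / (N - m), tolerance = 1e-10)
    } else {
      expect_lte(D * N / (N - m), abs(g$stat) + 1e-10)
    }
  }
})

test_that("weighted ES matches the independent fgsea implementation", {
  set.seed(23)
  rl <- rank_features(setNames(rnorm(300), sprintf("id%04d", 1:300)))
  for (i in 1:10) {
    members <- sample(rl$id, sample(5:30, 1))
    g <- gsea_es_nes(rl, list(s = members), B = 99, seed = 1, weight = 1)
    ref <- fgsea::calcGseaStat(
      setNames(rl$score, rl$id),
      selectedStats = sort(match(members, rl$id)),
      gseaParam = 1
    )
    expect_equal(g$stat, ref, tolerance = 1e-10)
  }
})

test_that("ES orientation: bottom-of-list sets score negative, reversal flips sign", {
  rl <- top_heavy_list(100)
  bottom <- gsea_es_nes(rl, list(s = rl$id[91:100]), B = 199, seed = 1)
  expect_lt(bottom$stat, 0)
  expect_lt(bottom$NES, 0)

  rev_rl <- rank_features(setNames(-rl$score, rl$id))
  flipped <- gsea_es_nes(rev_rl, list(s = rl$id[91:100]), B = 199, seed = 1)
  expect_gt(flipped$stat, 0)
  expect_equal(abs(flipped$stat), abs(bottom$stat), tolerance = 1e-10)
})

test_that("small sets are skipped with a record; q is BH across sets", {
  rl <- top_heavy_list(50)
  sets <- list(big = rl$id[1:8], tiny = rl$id[1:2], mid = rl$id[c(5, 20, 40)])
  g <- gsea_es_nes(rl, sets, B = 199, seed = 2, min_size = 3)
  expect_identical(attr(g, "skipped"), "tiny")
  expect_equal(g$q, p.adjust(g$p, "BH"))
})

test_that("specificity filter keeps case-specific sets ordered by summed NES", {
  mk <- function(names, q, nes) {
    structure(tibble::tibble(set_name = names, NES = nes, p = q, q = q),
      class = c("enrichment_result", class(tibble::tibble()))
    )
  }
  nm <- c("s1", "s2", "s3")
  caseA <- mk(nm, q = c(0.05, 0.05, 0.5), nes = c(1.5, 2.5, 1))
  caseB <- mk(nm, q = c(0.08, 0.15, 0.5), nes = c(2.0, 2.5, 1))
  ctrl <- mk(nm, q = c(0.5, 0.5, 0.01), nes = c(0.5, 0.5, 3))
  out <- specificity_filter(list(caseA, caseB), ctrl, q_case = 0.1, q_control = 0.2)
  expect_identical(out$set_name, "s1") # s2 fails one case, s3 enriched in control
  expect_equal(out$sum_NES, 3.5)

  # a set missing from one collection is excluded with a record
  caseB2 <- mk(nm[1:2], q = c(0.08, 0.15), nes = c(2, 2.5))
  out2 <- specificity_filter(list(caseA, caseB2), ctrl)
  expect_identical(attr(out2, "excluded"), "s3")
})

test_that("directed signatures are tested at the matching list ends", {
  rl <- top_heavy_list(100)
  sets <- gene_sets(
    list(inv_up = rl$id[1:8], prolif_down = rl$id[93:100]),
    direction = c("up", "down")
  )
  out <- directed_signature_test(rl, sets, B = 499, seed = 5)
  expect_setequal(out$end, c("top", "bottom"))
  expect_true(all(out$p <= 0.05))
})

test_that("kinase enrichment recovers a planted kinase and not decoys", {
  sim <- simulate_experiment(simulation_config(
    n_proteins = 300, sites_per_protein = c(1, 2),
    n_shared_up = 20, n_persistent_down = 10, n_resistant_up = 10,
    n_control_up = 10, seed = 7
  ))
  qt <- normalize_median_center(sim$quant)
  d <- list(
    feature_ttest(qt, contrast("A", list(cell_line = "cellA", state = "parental"),
      list(cell_line = "cellA", state = "resistant"))),
    feature_ttest(qt, contrast("B", list(cell_line = "cellB", state = "parental"),
      list(cell_line = "cellB", state = "resistant")))
  )
  kin <- kinase_enrichment(d, sim$site_sets, B = 1000, seed = 7)
  expect_true(kin$significant[kin$set_name == "shared_up"])
  expect_gt(kin$NES[kin$set_name == "shared_up"], 0)
  expect_false(kin$significant[kin$set_name == "decoy_shared_up_1"])
})
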
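small_cfg <- function(...) {
  simulation_config(
    n_proteins = 120, n_shared_up = 10, n_persistent_down = 10,
    n_resistant_up = 10, n_control_up = 10, ...
  )
}

test_that("simulation is bit-deterministic given the seed", {
  s1 <- simulate_experiment(small_cfg(seed = 5))
  s2 <- simulate_experiment(small_cfg(seed = 5))
  expect_identical(s1$quant$values, s2$quant$values)
  expect_identical(unclass(s1$sets), unclass(s2$sets))
  expect_identical(s1$truth$effects, s2$truth$effects)
  s3 <- simulate_experiment(small_cfg(seed = 6))
  expect_false(identical(s1$quant$values, s3$quant$values))
})

test_that("noise-free limit plants exact effects in both adaptation states", {
  cfg <- small_cfg(noise_sd = 0, missingness = FALSE, seed = 2)
  sim <- simulate_experiment(cfg)
  qt <- sim$quant
  planted <- sim$truth$site_programs$shared_up
  for (st in c("persistent", "resistant")) {
    a <- qt$values[, qt$samples$cell_line == "cellA" & qt$samples$state == "parental"]
    b <- qt$values[, qt$samples$cell_line == "cellA" & qt$samples$state == st]
    fc <- rowMeans(b) - rowMeans(a)
    expect_equal(unname(fc[planted]), rep(2, length(planted)))
  }
  # NRAS-like line does not receive the shared program
  a <- qt$values[, qt$samples$cell_line == "cellC" & qt$samples$state == "parental"]
  b <- qt$values[, qt$samples$cell_line == "cellC" & qt$samples$state == "resistant"]
  expect_equal(unname((rowMeans(b) - rowMeans(a))[planted]), rep(0, length(planted)))
})

test_that("planted programs are disjoint and decoys drawn from unplanted proteins", {
  sim <- simulate_experiment(small_cfg(seed = 9))
  progs <- sim$truth$programs
  expect_equal(length(unlist(progs)), length(unique(unlist(progs))))
  decoys <- unlist(sim$sets[grep("^decoy", names(sim$sets))])
  expect_length(intersect(decoys, unlist(progs)), 0)
  expect_equal(lengths(sim$sets)[["decoy_shared_up_1"]], lengths(sim$sets)[["shared_up"]])
})

test_that("observed fold change concentrates on the planted effect (LLN)", {
  cfg <- simulation_config(
    n_proteins = 520, sites_per_protein = c(1, 1),
    n_shared_up = 500, n_persistent_down = 0, n_resistant_up = 0,
    n_control_up = 0, n_decoy_sets = 0,
    noise_sd = 0.5, missingness = FALSE, seed = 31
  )
  sim <- simulate_experiment(cfg)
  qt <- sim$quant
  planted <- sim$truth$site_programs$shared_up
  a <- qt$values[planted, qt$samples$cell_line == "cellA" & qt$samples$state == "parental"]
  b <- qt$values[planted, qt$samples$cell_line == "cellA" & qt$samples$state == "resistant"]
  fc <- rowMeans(b) - rowMeans(a)
  expect_lt(abs(mean(fc) - 2), 0.1)
})

test_that("lowering the missingness midpoint increases the detected fraction", {
  det <- function(mid) {
    sim <- simulate_experiment(small_cfg(
      seed = 4, missing_midpoint = mid,
      baseline_mean = 16, baseline_sd = 1.5
    ))
    mean(!is.na(sim$quant$values))
  }
  fr <- vapply(c(18, 16, 14, 10), det, numeric(1))
  expect_true(all(diff(fr) > 0))
  # low-intensity features are preferentially censored
  sim <- simulate_experiment(small_cfg(seed = 4, missing_midpoint = 16,
    baseline_mean = 16, baseline_sd = 1.5))
  base_rank <- rank(rowMeans(sim$quant$values, na.rm = TRUE))
  n_miss <- rowSums(is.na(sim$quant$values))
  expect_lt(cor(base_rank, n_miss, method = "spearman"), 0)
})

test_that("expression twin inherits protein-level effects", {
  cfg <- small_cfg(noise_sd = 0, expression_noise_sd = 0, missingness = FALSE, seed = 8)
  sim <- simulate_experiment(cfg)
  expr <- make_expression_twin(sim$truth)
  a <- expr$values[, expr$samples$cell_line == "cellA" & expr$samples$state == "parental"]
  b <- expr$values[, expr$samples$cell_line == "cellA" & expr$samples$state == "resistant"]
  fc <- rowMeans(b) - rowMeans(a)
  expect_equal(unname(fc[sim$truth$programs$shared_up]),
    rep(2, length(sim$truth$programs$shared_up)))
  expect_equal(unname(fc[sim$truth$programs$persistent_down]),
    rep(0, length(sim$truth$programs$persistent_down)))
  # deterministic
  expect_identical(expr$values, make_expression_twin(sim$truth)$values)
})

test_that("expression fold changes track planted effects at realistic noise", {
  cfg <- small_cfg(expression_noise_sd = 0.3, seed = 12)
  sim <- simulate_experiment(cfg)
  expr <- make_expression_twin(sim$truth)
  truth_fc <- dplyr::distinct(
    dplyr::filter(sim$truth$effects, cell_line == "cellA", state == "resistant"),
    protein_id, effect
  )
  a <- expr$values[, expr$samples$cell_line == "cellA" & expr$samples$state == "parental"]
  b <- expr$values[, expr$samples$cell_line == "cellA" & expr$samples$state == "resistant"]
  fc <- rowMeans(b) - rowMeans(a)
  expect_gt(cor(truth_fc$effect[match(names(fc), truth_fc$protein_id)], fc), 0.9)
})

test_that("decoy sets are exchangeable with planted sets under zero effect", {
  D_of <- function(set, ranked) ks_permutation_test(ranked, set, B = 99, seed = 1)$stat
  Ds <- sapply(1:30, function(i) {
    cfg <- small_cfg(
      seed = 100 + i, effect_shared_up = 0, effect_persistent_down = 0,
      effect_resistant_up = 0, effect_control_up = 0
    )
    sim <- simulate_experiment(cfg)
    d <- feature_ttest(
      normalize_median_center(sim$quant),
      contrast("c", list(cell_line = "cellA", state = "parental"),
        list(cell_line = "cellA", state = "resistant"))
    )
    ranked <- rank_features(tibble::tibble(
      id = d$feature_id[!is.na(d$log2fc)], score = d$log2fc[!is.na(d$log2fc)]
    ))
    c(
      planted = D_of(sim$site_sets[["shared_up"]], ranked),
      decoy = D_of(sim$site_sets[["decoy_shared_up_1"]], ranked)
    )
  })
  ratio <- mean(Ds["planted", ]) / mean(Ds["decoy", ])
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.6)
})

test_that("degenerate configs are rejected", {
  expect_error(small_cfg(replicates = 0), "replicates")
  expect_error(
    simulation_config(n_proteins = 30, n_shared_up = 20, n_persistent_down = 20),
    "exceed"
  )
  expect_error(small_cfg(effect_shared_up = Inf), "finite")
})
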
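#' Configure an end-to-end analysis run
#'
#' Bundles the synthetic-experiment design and every analysis setting
#' (thresholds, permutation counts, seeds, RRHO step) for
#' [run_pipeline()]. All randomness is governed by explicit seeds, so a
#' config determines the run byte-for-byte.
#'
#' @param sim a [simulation_config()] describing the input experiment.
#' @param filter_preset_name phospho filter preset (see [filter_preset()]).
#' @param alpha_concordance FDR threshold declaring a site significantly
#'   altered for the direction table; defaults to the phospho profiles' own
#'   FDR threshold (0.2).
#' @param B_signature permutations for the signature KS test.
#' @param B_sets permutations per set for GSEA/kinase enrichment.
#' @param enrichment_seed seed for all permutation tests.
#' @param gsea_weight running-sum weight.
#' @param q_case,q_control specificity-filter thresholds.
#' @param q_kinase kinase FDR threshold.
#' @param rrho_step RRHO rank step (`NULL` = `max(1, floor(N/100))`).
#' @param top_k top-list size for planted-target recovery.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            filter_preset_name = "phospho_ttest",
                            alpha_concordance = 0.2,
                            B_signature = 10000,
                            B_sets = 1000,
                            enrichment_seed = 17,
                            gsea_weight = 1,
                            q_case = 0.1, q_control = 0.2,
                            q_kinase = 0.2,
                            rrho_step = NULL,
                            top_k = 40) {
  stopifnot(inherits(sim, "simulation_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cl <- config$sim$cell_lines
  rtk <- cl$cell_line[cl$mechanism == "RTK"]
  nras <- cl$cell_line[cl$mechanism == "NRAS"]
  if (length(rtk) < 2) abort("pipeline needs >= 2 RTK-like case lines")
  if (length(nras) < 1) abort("pipeline needs an NRAS-like control line")
  for (i in seq_len(nrow(cl))) {
    missing <- setdiff(c("parental", "persistent", "resistant"), cl$states[[i]])
    if (length(missing)) {
      abort(sprintf(
        "cell line '%s' lacks state(s): %s",
        cl$cell_line[i], paste(missing, collapse = ", ")
      ))
    }
  }
  invisible(config)
}

state_contrast <- function(line, state) {
  contrast(
    paste0(line, "_", substr(state, 1, 1), "vP"),
    group_a = list(cell_line = line, state = "parental"),
    group_b = list(cell_line = line, state = state)
  )
}

#' Run the integrative analysis pipeline on a synthetic experiment
#'
#' Orchestrates the full analysis: simulate -> median-center -> per-contrast
#' differential phospho statistics -> direction concordance (Fisher exact)
#' between the two case resistant pairs -> threshold filter -> combined
#' perturbation score with planted-target recovery -> expression twin ->
#' summed fold-change signature with permutation-KS enrichment of the
#' planted mesenchymal-like program -> RRHO between the two case expression
#' rankings -> pairwise signature correlation with hierarchical clustering
#' -> per-line TF-style set enrichment with the case/control specificity
#' filter -> kinase-substrate enrichment. Every stage writes a plain-text
#' intermediate under `out_dir` and the run ends with a machine-readable
#' `summary.json` stamped with the config hash and seeds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The summary (a list), invisibly; all artifacts under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("adaptomics_run_")) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cl <- config$sim$cell_lines
  rtk <- cl$cell_line[cl$mechanism == "RTK"][1:2]
  nras <- cl$cell_line[cl$mechanism == "NRAS"][1]

  sim <- simulate_experiment(config$sim)
  qt <- normalize_median_center(sim$quant)
  write_quant_table(qt, file.path(out_dir, "phospho_normalized.tsv"))

  # differential phospho statistics: persistent and resistant vs parental
  diffs <- list()
  for (line in c(rtk, nras)) {
    for (st in c("persistent", "resistant")) {
      ct <- state_contrast(line, st)
      diffs[[ct$name]] <- feature_ttest(qt, ct)
      readr::write_tsv(
        as_tibble(diffs[[ct$name]]),
        file.path(out_dir, paste0("diff_", ct$name, ".tsv"))
      )
    }
  }

  # direction concordance between the two case persistent pairs (both
  # up- and down-regulated programs are planted in that state)
  resA <- diffs[[paste0(rtk[1], "_rvP")]]
  resB <- diffs[[paste0(rtk[2], "_rvP")]]
  dtab <- build_direction_table(
    diffs[[paste0(rtk[1], "_pvP")]], diffs[[paste0(rtk[2], "_pvP")]],
    sig_policy = "either", alpha = config$alpha_concordance
  )
  concord_p <- fisher_exact_2x2(dtab)

  # preset threshold filter on a persistent-state profile
  persA <- diffs[[paste0(rtk[1], "_pvP")]]
  filt <- apply_filter(persA, config$filter_preset_name)

  # combined perturbation score over the four case contrasts
  case_diffs <- diffs[paste0(rep(rtk, each = 2), c("_pvP", "_rvP"))]
  pscore <- combined_perturbation_score(case_diffs)
  readr::write_tsv(as_tibble(pscore), file.path(out_dir, "perturbation_scores.tsv"))
  recovery <- recover_shared_targets(pscore, sim$truth, k = config$top_k)

  # expression twin: per-line resistant-vs-parental fold-change rankings
  expr <- make_expression_twin(sim$truth, config$sim)
  expr_rank <- list()
  expr_diff <- list()
  for (line in c(rtk, nras)) {
    d <- feature_ttest(expr, state_contrast(line, "resistant"))
    expr_diff[[line]] <- d
    expr_rank[[line]] <- rank_features(tibble(id = d$feature_id, score = d$log2fc))
    write_rnk(expr_rank[[line]], file.path(out_dir, paste0("expr_", line, ".rnk")))
  }
  sum_rank <- sum_fold_change_signature(expr_diff[rtk])
  write_rnk(sum_rank, file.path(out_dir, "expr_case_sum.rnk"))
  write_gmt(sim$sets, file.path(out_dir, "gene_sets.gmt"))

  # mesenchymal-like program enrichment in the summed case signature
  ks <- ks_permutation_test(
    sum_rank, sim$sets["resistant_up"],
    B = config$B_signature, seed = config$enrichment_seed
  )

  # RRHO between the two case expression rankings
  rr <- rrho_map(expr_rank[[rtk[1]]], expr_rank[[rtk[2]]], step = config$rrho_step)
  write_rrho(
    rr, file.path(out_dir, "rrho_matrix.tsv"),
    file.path(out_dir, "rrho_summary.json")
  )

  # signature correlation and clustering over all per-line fc signatures
  sig_wide <- tibble(id = expr_diff[[1]]$feature_id)
  for (line in names(expr_diff)) {
    sig_wide[[paste0(line, "_RvP")]] <- expr_diff[[line]]$log2fc
    pers <- feature_ttest(expr, state_contrast(line, "persistent"))
    sig_wide[[paste0(line, "_PvP")]] <- pers$log2fc
  }
  sm <- hierarchical_cluster(pairwise_signature_correlation(sig_wide))
  readr::write_tsv(tidy(sm), file.path(out_dir, "signature_correlations.tsv"))

  # TF-style enrichment per line + specificity filter (cases vs control)
  tf <- lapply(c(rtk, nras), function(line) {
    gsea_es_nes(expr_rank[[line]], sim$sets,
      B = config$B_sets,
      seed = config$enrichment_seed, weight = config$gsea_weight
    )
  })
  names(tf) <- c(rtk, nras)
  spec <- specificity_filter(tf[rtk], tf[[nras]],
    q_case = config$q_case, q_control = config$q_control
  )
  readr::write_tsv(spec, file.path(out_dir, "tf_specific_sets.tsv"))

  # kinase-substrate enrichment on the case resistant phospho profiles
  kin <- kinase_enrichment(
    list(resA, resB), sim$site_sets,
    B = config$B_sets, seed = config$enrichment_seed,
    weight = config$gsea_weight, q_max = config$q_kinase
  )
  readr::write_tsv(
    dplyr::select(as_tibble(kin), -"leading_edge"),
    file.path(out_dir, "kinase_enrichment.tsv")
  )

  summary <- list(
    provenance = list(
      config_hash = rlang::hash(config),
      sim_seed = config$sim$seed,
      enrichment_seed = config$enrichment_seed,
      n_features = nrow(qt$values),
      n_samples = ncol(qt$values)
    ),
    concordance = list(
      table = as.vector(unclass(dtab)),
      fisher_p = concord_p,
      n_zero_excluded = attr(dtab, "n_zero_excluded")
    ),
    filter = list(
      preset = config$filter_preset_name,
      n_survivors = attr(filt, "n_survivors")
    ),
    perturbation = list(
      top_k = config$top_k,
      recovery = recovery,
      top_proteins = head(pscore$protein_id[order(pscore$rank_up)], config$top_k)
    ),
    signature_enrichment = list(stat_D = ks$stat, p = ks$p),
    rrho = list(
      max_neglog10p = rr$summary$max,
      at = as.list(rr$summary$at)
    ),
    tf_specific = list(n_sets = nrow(spec), sets = spec$set_name),
    kinase = list(significant = kin$set_name[kin$significant]),
    signature_clusters = as.list(setNames(
      cut_signature_tree(sm, 2)$cluster,
      cut_signature_tree(sm, 2)$signature
    ))
  )
  jsonlite::write_json(
    summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(summary)
}
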
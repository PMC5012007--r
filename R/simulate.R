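#' Configure a synthetic adaptation-state experiment
#'
#' Defines the generative model used to test every analysis stage without
#' external downloads. The design mirrors a kinase-inhibitor adaptation
#' study: several cell lines, each profiled in `parental`, `persistent`
#' (short-term drug-exposed) and `resistant` (chronically exposed) states
#' with replicates; log-normal label-free intensities (additive Gaussian
#' noise on the log2 scale); intensity-dependent missingness
#' (left-censoring); and planted effect programs:
#'
#' * `shared_up` — upregulated in *both* persistent and resistant states
#'   (the shared-target program a combined perturbation score should find);
#' * `persistent_down` — growth-arrest-like, down in the persistent state of
#'   every line;
#' * `resistant_up` — mesenchymal-like, up only in the resistant state;
#' * `control_up` — MAPK-reactivation-like, up only in the resistant state
#'   of NRAS-like lines (the specificity-control program).
#'
#' Mechanism labels gate the programs: `shared_up` and `resistant_up` apply
#' to RTK-like lines only, `control_up` to NRAS-like lines only, and
#' `persistent_down` to all lines.
#'
#' @param n_proteins number of proteins.
#' @param sites_per_protein integer range `c(min, max)`; each protein gets a
#'   uniform number of phospho-sites in this range.
#' @param cell_lines data frame with columns `cell_line`, `mechanism`
#'   (`"RTK"` or `"NRAS"`) and `states` (list-column of state names).
#' @param replicates replicates per (cell line, state) group.
#' @param baseline_mean,baseline_sd mean/sd of per-feature baseline log2
#'   intensity.
#' @param noise_sd replicate noise sd, log2 units.
#' @param n_shared_up,n_persistent_down,n_resistant_up,n_control_up planted
#'   program sizes (proteins; disjoint).
#' @param effect_shared_up,effect_persistent_down,effect_resistant_up,effect_control_up
#'   planted effect sizes in log2 units.
#' @param missing_midpoint,missing_slope logistic detection model: an entry
#'   with true log2 intensity x is detected with probability
#'   `plogis(missing_slope * (x - missing_midpoint))`. Set
#'   `missing_slope = 0` and `missing_midpoint = -Inf` for no missingness
#'   (see `missingness`).
#' @param missingness `TRUE`/`FALSE` master switch.
#' @param expression_noise_sd noise sd for the expression twin.
#' @param n_decoy_sets decoy gene sets of matched size per planted program.
#' @param seed integer seed; all outputs are deterministic given the config.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 1000,
                              sites_per_protein = c(1, 3),
                              cell_lines = default_cell_lines(),
                              replicates = 3,
                              baseline_mean = 20, baseline_sd = 2,
                              noise_sd = 0.5,
                              n_shared_up = 20, effect_shared_up = 2,
                              n_persistent_down = 30, effect_persistent_down = -2,
                              n_resistant_up = 30, effect_resistant_up = 2,
                              n_control_up = 20, effect_control_up = 2,
                              missing_midpoint = 14, missing_slope = 1,
                              missingness = TRUE,
                              expression_noise_sd = 0.3,
                              n_decoy_sets = 1,
                              seed = 1) {
  cell_lines <- as_tibble(cell_lines)
  stopifnot(
    n_proteins >= 1, replicates >= 1,
    length(sites_per_protein) == 2, sites_per_protein[1] >= 1,
    sites_per_protein[2] >= sites_per_protein[1],
    all(c("cell_line", "mechanism", "states") %in% names(cell_lines)),
    all(cell_lines$mechanism %in% c("RTK", "NRAS"))
  )
  n_planted <- n_shared_up + n_persistent_down + n_resistant_up + n_control_up
  biggest <- max(n_shared_up, n_persistent_down, n_resistant_up, n_control_up)
  if (n_planted + biggest * (n_decoy_sets > 0) > n_proteins) {
    abort("planted programs (plus decoy pool) exceed n_proteins")
  }
  effs <- c(effect_shared_up, effect_persistent_down, effect_resistant_up, effect_control_up)
  if (any(!is.finite(effs))) abort("effect sizes must be finite")
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_cell_lines <- function() {
  tibble(
    cell_line = c("cellA", "cellB", "cellC"),
    mechanism = c("RTK", "RTK", "NRAS"),
    states = list(
      c("parental", "persistent", "resistant"),
      c("parental", "persistent", "resistant"),
      c("parental", "persistent", "resistant")
    )
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d proteins, %d lines, %d reps, noise_sd=%.2f, seed=%d\n",
    x$n_proteins, nrow(x$cell_lines), x$replicates, x$noise_sd, x$seed
  ))
  invisible(x)
}

# planted per-protein effect for one (mechanism, state) cell
program_effect <- function(cfg, program, mechanism, state) {
  switch(program,
    shared_up = if (mechanism == "RTK" && state %in% c("persistent", "resistant")) {
      cfg$effect_shared_up
    } else 0,
    persistent_down = if (state == "persistent") cfg$effect_persistent_down else 0,
    resistant_up = if (mechanism == "RTK" && state == "resistant") {
      cfg$effect_resistant_up
    } else 0,
    control_up = if (mechanism == "NRAS" && state == "resistant") {
      cfg$effect_control_up
    } else 0,
    0
  )
}

#' Simulate a synthetic adaptation-state experiment
#'
#' Draws a phospho-site level quantification table, the matching gene-set
#' collection (planted programs plus size-matched decoy sets, at protein and
#' at site level) and the ground truth, deterministically for a given config.
#' Observed log2 value = baseline + planted effect + N(0, noise_sd^2);
#' entries are masked missing with the configured intensity-dependent
#' (left-censoring) probability.
#'
#' @param config a [simulation_config].
#' @return A list of class `simulated_experiment` with elements
#'   `quant` ([quant_table], phospho-site level), `sets` (protein-level
#'   [gene_sets]), `site_sets` (feature-level [gene_sets]), and
#'   `truth` (list: `effects` tibble of per-feature true effects per
#'   (cell_line, state), `programs`, `site_programs`).
#' @export
#' @examples
#' sim <- simulate_experiment(simulation_config(n_proteins = 50, seed = 7))
#' sim$quant
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)

  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
  n_sites <- sample(seq(cfg$sites_per_protein[1], cfg$sites_per_protein[2]),
    cfg$n_proteins,
    replace = TRUE
  )
  features <- tibble(
    protein_id = rep(proteins, n_sites),
    site_label = paste0("S", unlist(lapply(n_sites, seq_len)) * 10 + 3)
  )
  features$feature_id <- paste0(features$protein_id, "_", features$site_label)

  # disjoint planted programs at the protein level
  sizes <- c(
    shared_up = cfg$n_shared_up, persistent_down = cfg$n_persistent_down,
    resistant_up = cfg$n_resistant_up, control_up = cfg$n_control_up
  )
  sizes <- sizes[sizes > 0]
  pool <- sample(proteins)
  programs <- list()
  off <- 0
  for (nm in names(sizes)) {
    programs[[nm]] <- sort(pool[off + seq_len(sizes[[nm]])])
    off <- off + sizes[[nm]]
  }
  unplanted <- sort(pool[-seq_len(off)])

  # sample sheet
  design <- tidyr::unnest(cfg$cell_lines, "states")
  names(design)[names(design) == "states"] <- "state"
  samples <- tidyr::crossing(design, replicate = seq_len(cfg$replicates))
  samples$sample <- sprintf(
    "%s.%s.%d", samples$cell_line, samples$state, samples$replicate
  )
  samples <- samples[c("sample", "cell_line", "state", "replicate", "mechanism")]

  baseline <- rnorm(nrow(features), cfg$baseline_mean, cfg$baseline_sd)

  # per-feature true effect for each (cell_line, state)
  prog_of <- setNames(rep(names(programs), lengths(programs)), unlist(programs))
  feat_prog <- unname(prog_of[features$protein_id])
  cells <- unique(samples[c("cell_line", "state", "mechanism")])
  eff_list <- lapply(seq_len(nrow(cells)), function(i) {
    eff <- numeric(nrow(features))
    has <- !is.na(feat_prog)
    if (any(has)) {
      eff[has] <- vapply(
        feat_prog[has],
        function(p) program_effect(cfg, p, cells$mechanism[i], cells$state[i]),
        numeric(1)
      )
    }
    tibble(
      feature_id = features$feature_id, protein_id = features$protein_id,
      cell_line = cells$cell_line[i], state = cells$state[i], effect = eff
    )
  })
  effects <- dplyr::bind_rows(eff_list)

  eff_key <- paste(effects$cell_line, effects$state)
  eff_mat <- matrix(0, nrow(features), nrow(samples))
  for (j in seq_len(nrow(samples))) {
    key <- paste(samples$cell_line[j], samples$state[j])
    eff_mat[, j] <- effects$effect[eff_key == key]
  }

  true_val <- baseline + eff_mat
  obs <- true_val + matrix(
    rnorm(length(true_val), 0, cfg$noise_sd),
    nrow(features), nrow(samples)
  )
  if (isTRUE(cfg$missingness) && cfg$missing_slope > 0) {
    p_det <- plogis(cfg$missing_slope * (true_val - cfg$missing_midpoint))
    obs[matrix(runif(length(obs)), nrow(obs)) > p_det] <- NA_real_
  }

  qt <- quant_table(obs, features, samples[, 1:4], scale = "log2")

  # protein-level sets: planted programs + matched-size decoys from unplanted
  set_list <- programs
  dirs <- c(
    shared_up = "up", persistent_down = "down",
    resistant_up = "up", control_up = "up"
  )[names(programs)]
  decoy_pool <- unplanted
  for (nm in names(programs)) {
    for (d in seq_len(cfg$n_decoy_sets)) {
      take <- sample(length(decoy_pool), length(programs[[nm]]))
      set_list[[sprintf("decoy_%s_%d", nm, d)]] <- sort(decoy_pool[take])
      dirs <- c(dirs, "undirected")
    }
  }
  sets <- gene_sets(set_list, direction = unname(dirs))

  site_sets <- gene_sets(lapply(
    set_list,
    function(m) features$feature_id[features$protein_id %in% m]
  ), direction = unname(dirs))
  site_programs <- lapply(
    programs,
    function(m) features$feature_id[features$protein_id %in% m]
  )

  structure(
    list(
      quant = qt, sets = sets, site_sets = site_sets,
      truth = list(
        effects = effects, programs = programs,
        site_programs = site_programs, config = cfg
      )
    ),
    class = "simulated_experiment"
  )
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("<simulated_experiment>\n")
  print(x$quant)
  invisible(x)
}

#' Generate the matched gene-expression twin of a simulated experiment
#'
#' Produces a one-row-per-protein expression table whose effects are
#' inherited from the protein-level ground truth of [simulate_experiment()],
#' emulating the transcriptomic counterpart of the proteomic profiles (used
#' by the signature enrichment, RRHO and TF-activity stages). Same design,
#' same mechanism gating, independent noise; complete (no missingness), as
#' for array/RNA-seq data. Deterministic given the config seed.
#'
#' @param truth the `truth` element of a `simulated_experiment` (or the
#'   object itself).
#' @param config the same [simulation_config]; defaults to the one stored in
#'   `truth`.
#' @return A [quant_table] with one feature per protein (gene).
#' @export
make_expression_twin <- function(truth, config = NULL) {
  if (inherits(truth, "simulated_experiment")) truth <- truth$truth
  cfg <- config %||% truth$config
  stopifnot(inherits(cfg, "simulation_config"))
  if (!identical(sort(unique(truth$effects$protein_id)), sort(unique(truth$effects$protein_id)))) {
    abort("truth/config mismatch")
  }
  if (length(unique(truth$effects$protein_id)) != cfg$n_proteins) {
    abort("truth/config mismatch: protein universe differs")
  }
  set.seed(cfg$seed + 1000003L)

  prot_eff <- dplyr::distinct(
    truth$effects, .data$protein_id, .data$cell_line, .data$state, .data$effect
  )
  proteins <- sort(unique(prot_eff$protein_id))
  design <- tidyr::unnest(cfg$cell_lines, "states")
  names(design)[names(design) == "states"] <- "state"
  samples <- tidyr::crossing(design, replicate = seq_len(cfg$replicates))
  samples$sample <- sprintf(
    "%s.%s.%d", samples$cell_line, samples$state, samples$replicate
  )
  samples <- samples[c("sample", "cell_line", "state", "replicate")]

  baseline <- rnorm(length(proteins), cfg$baseline_mean, cfg$baseline_sd)
  key <- paste(prot_eff$cell_line, prot_eff$state)
  eff_mat <- matrix(0, length(proteins), nrow(samples))
  ord <- order(prot_eff$protein_id)
  for (j in seq_len(nrow(samples))) {
    kj <- paste(samples$cell_line[j], samples$state[j])
    sel <- ord[key[ord] == kj]
    eff_mat[, j] <- prot_eff$effect[sel]
  }
  obs <- baseline + eff_mat + matrix(
    rnorm(length(eff_mat), 0, cfg$expression_noise_sd),
    length(proteins), nrow(samples)
  )
  quant_table(
    obs,
    features = tibble(feature_id = proteins, protein_id = proteins),
    samples = samples, scale = "log2"
  )
}
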
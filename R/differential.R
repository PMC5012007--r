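#' Median-center each sample column
#'
#' Subtracts the per-column median over present values, so every sample has
#' median 0 on the log2 scale. The missing mask is unchanged; idempotent.
#'
#' @param table a log2-scale [quant_table].
#' @return A [quant_table].
#' @export
normalize_median_center <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (table$scale != "log2") abort("median centering requires a log2-scale table")
  n_present <- colSums(!is.na(table$values))
  if (any(n_present < 2)) {
    abort(paste0(
      "column(s) with <2 present values: ",
      paste(table$samples$sample[n_present < 2], collapse = ", ")
    ))
  }
  med <- apply(table$values, 2, median, na.rm = TRUE)
  table$values <- sweep(table$values, 2, med)
  table
}

# p-value sentinel for zero pooled variance with unequal means
P_SENTINEL <- 1e-300

# signed log-t score; `variant` chooses what gets logged
signed_score <- function(log2fc, p, stat, variant = c("log_p", "log_t"),
                         cap = 300) {
  variant <- match.arg(variant)
  s <- switch(variant,
    log_p = sign(log2fc) * (-log10(p)),
    log_t = sign(log2fc) * log10(pmax(abs(stat), 1))
  )
  pmin(pmax(s, -cap), cap)
}

#' Per-feature two-group Student's t-test
#'
#' Pooled-variance two-sided Student's t for every feature of a
#' quantification table under a [contrast()] (Welch available via
#' `var_equal = FALSE`). Reports `log2fc = mean_b - mean_a` and the signed
#' log-t score `s = sign(log2fc) * (-log10 p)` (see `score_variant`);
#' the `stat` column follows the `t.test(a, b)` sign convention (based on
#' group_a − group_b), so `sign(stat) = -sign(log2fc)`. Benjamini–Hochberg
#' `q` is computed across all tested (non-flagged) features. Features with
#' fewer than 2 present replicates in either group are flagged
#' (`"insufficient_replicates"`), never silently dropped; zero pooled
#' variance with unequal means yields the machine-minimum p sentinel
#' (1e-300) and flag `"zero_variance"`.
#'
#' @param table a [quant_table] (log2 scale).
#' @param contrast a [contrast()].
#' @param var_equal pooled variance (default) or Welch.
#' @param score_variant `"log_p"` for sign(log2fc)·(−log10 p) (default) or
#'   `"log_t"` for sign(log2fc)·log10|t|.
#' @return A tibble of class `differential_result` with columns `feature_id`,
#'   `protein_id`, `site_label`, `log2fc`, `stat`, `p`, `q`, `s`, `n_a`,
#'   `n_b`, `flag`; attributes `contrast` and `test`.
#' @export
feature_ttest <- function(table, contrast, var_equal = TRUE,
                          score_variant = "log_p") {
  stopifnot(inherits(table, "quant_table"))
  grp <- resolve_contrast(table, contrast)
  A <- table$values[, grp$a, drop = FALSE]
  B <- table$values[, grp$b, drop = FALSE]
  na <- rowSums(!is.na(A))
  nb <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE)
  mb <- rowMeans(B, na.rm = TRUE)
  va <- apply(A, 1, var, na.rm = TRUE)
  vb <- apply(B, 1, var, na.rm = TRUE)

  ok <- na >= 2 & nb >= 2
  log2fc <- ifelse(na >= 1 & nb >= 1, mb - ma, NA_real_)
  t_stat <- p <- rep(NA_real_, nrow(A))
  flag <- ifelse(ok, "", "insufficient_replicates")

  if (var_equal) {
    sp2 <- (pmax(na - 1, 0) * va + pmax(nb - 1, 0) * vb) / pmax(na + nb - 2, 1)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * pmax(na - 1, 1)) + vb^2 / (nb^2 * pmax(nb - 1, 1)))
  }
  pos <- ok & se > 0
  t_stat[pos] <- (ma[pos] - mb[pos]) / se[pos]
  p[pos] <- 2 * pt(-abs(t_stat[pos]), df[pos])

  zerovar <- ok & se == 0
  eq <- zerovar & (mb - ma == 0)
  ne <- zerovar & (mb - ma != 0)
  t_stat[eq] <- 0
  p[eq] <- 1
  t_stat[ne] <- -sign(mb[ne] - ma[ne]) * Inf
  p[ne] <- P_SENTINEL
  flag[ne] <- "zero_variance"

  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  s <- rep(NA_real_, length(p))
  s[ok] <- signed_score(log2fc[ok], p[ok], t_stat[ok], variant = score_variant)

  out <- tibble(
    feature_id = table$features$feature_id,
    protein_id = table$features$protein_id,
    site_label = table$features$site_label,
    log2fc = unname(log2fc), stat = unname(t_stat), p = unname(p),
    q = unname(q), s = unname(s),
    n_a = as.integer(unname(na)), n_b = as.integer(unname(nb)),
    flag = unname(flag)
  )
  structure(out,
    contrast = contrast$name, test = "student_t",
    class = c("differential_result", class(tibble()))
  )
}

#' Per-feature one-way analysis of variance
#'
#' One-way F statistic and p per feature across three or more groups,
#' with all pairwise group-mean differences (log2 fold changes) reported
#' alongside; `log2fc` holds the pairwise difference of largest magnitude,
#' which the fold-change filters act on.
#'
#' @param table a [quant_table].
#' @param groups named list of >=3 sample selectors
#'   (`list(cell_line =, state =)`), or a character vector of group labels
#'   of length `ncol(table$values)`.
#' @return A tibble of class `differential_result` (with `stat` = F); per-pair
#'   mean differences in columns `log2fc_<g2>_vs_<g1>`.
#' @export
feature_anova <- function(table, groups) {
  stopifnot(inherits(table, "quant_table"))
  if (is.character(groups) && length(groups) == ncol(table$values)) {
    labels <- groups
  } else {
    if (length(groups) < 3) abort("feature_anova needs >=3 groups")
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    labels <- rep(NA_character_, ncol(table$values))
    for (nm in names(groups)) {
      idx <- table$samples$sample %in% select_samples(table$samples, groups[[nm]])
      if (any(!is.na(labels[idx]))) abort("group selectors overlap")
      labels[idx] <- nm
    }
  }
  keep <- !is.na(labels)
  V <- table$values[, keep, drop = FALSE]
  labels <- labels[keep]
  gs <- unique(labels)
  if (length(gs) < 3) abort("feature_anova needs >=3 groups")

  n_g <- sapply(gs, function(g) rowSums(!is.na(V[, labels == g, drop = FALSE])))
  m_g <- sapply(gs, function(g) rowMeans(V[, labels == g, drop = FALSE], na.rm = TRUE))
  ss_g <- sapply(gs, function(g) {
    W <- V[, labels == g, drop = FALSE]
    rowSums((W - rowMeans(W, na.rm = TRUE))^2, na.rm = TRUE)
  })
  if (is.null(dim(n_g))) {
    n_g <- matrix(n_g, nrow = 1); m_g <- matrix(m_g, nrow = 1)
    ss_g <- matrix(ss_g, nrow = 1)
  }
  ok <- rowSums(n_g >= 2) == length(gs)
  N <- rowSums(n_g)
  grand <- rowSums(n_g * m_g, na.rm = TRUE) / N
  ssb <- rowSums(n_g * (m_g - grand)^2, na.rm = TRUE)
  ssw <- rowSums(ss_g)
  df1 <- length(gs) - 1
  df2 <- N - length(gs)

  F_stat <- p <- rep(NA_real_, nrow(V))
  flag <- ifelse(ok, "", "insufficient_replicates")
  pos <- ok & ssw > 0
  F_stat[pos] <- (ssb[pos] / df1) / (ssw[pos] / df2[pos])
  p[pos] <- pf(F_stat[pos], df1, df2[pos], lower.tail = FALSE)
  zer <- ok & ssw == 0
  F_stat[zer & ssb == 0] <- 0
  p[zer & ssb == 0] <- 1
  F_stat[zer & ssb > 0] <- Inf
  p[zer & ssb > 0] <- P_SENTINEL
  flag[zer & ssb > 0] <- "zero_variance"

  pairs <- utils::combn(seq_along(gs), 2)
  pairfc <- apply(pairs, 2, function(ij) m_g[, ij[2]] - m_g[, ij[1]])
  if (is.null(dim(pairfc))) pairfc <- matrix(pairfc, nrow = 1)
  colnames(pairfc) <- apply(pairs, 2, function(ij) {
    paste0("log2fc_", gs[ij[2]], "_vs_", gs[ij[1]])
  })
  imax <- max.col(abs(pairfc), ties.method = "first")
  log2fc <- pairfc[cbind(seq_len(nrow(pairfc)), imax)]

  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  s <- rep(NA_real_, length(p))
  s[ok] <- signed_score(log2fc[ok], p[ok], F_stat[ok])

  out <- dplyr::bind_cols(
    tibble(
      feature_id = table$features$feature_id,
      protein_id = table$features$protein_id,
      site_label = table$features$site_label,
      log2fc = unname(log2fc), stat = unname(F_stat), p = unname(p),
      q = unname(q), s = unname(s),
      n_a = as.integer(unname(n_g[, 1])), n_b = as.integer(unname(n_g[, 2])),
      flag = unname(flag)
    ),
    as_tibble(pairfc)
  )
  structure(out,
    contrast = paste(gs, collapse = "|"), test = "anova",
    class = c("differential_result", class(tibble()))
  )
}

#' @export
glance.differential_result <- function(x, ...) {
  tibble(
    contrast = attr(x, "contrast"), test = attr(x, "test"),
    n_features = nrow(x), n_tested = sum(x$flag %in% c("", "zero_variance")),
    n_flagged = sum(x$flag != "")
  )
}

#' Significance / fold-change filter specifications
#'
#' `filter_spec()` pairs an FDR (or raw-p, for the ANOVA preset) threshold
#' with a minimum linear fold change. `filter_preset()` returns the named
#' presets used in the analysis:
#' * `"proteome_anova"` — ANOVA p < 0.05 and 3-fold average up/down
#'   regulation (whole-proteome state comparison);
#' * `"phospho_ttest"` — Student's-t BH FDR q < 0.2 and 2-fold regulation
#'   (phospho-site persistent-vs-parental profiles);
#' * `"ecm_ttest"` — BH FDR q < 0.1, no fold requirement (ECM protein
#'   profiles).
#'
#' @param max_q threshold on q (t-test specs) or on raw p (ANOVA specs),
#'   in (0, 1].
#' @param min_abs_fold minimum linear fold change (>= 1); applied as
#'   `|log2fc| >= log2(min_abs_fold)`.
#' @param test `"student_t"` or `"anova"`.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(max_q, min_abs_fold = 1, test = c("student_t", "anova")) {
  test <- match.arg(test)
  if (!(max_q > 0 && max_q <= 1)) abort("max_q must be in (0, 1]")
  if (min_abs_fold < 1) abort("min_abs_fold must be >= 1")
  structure(list(max_q = max_q, min_abs_fold = min_abs_fold, test = test),
    class = "filter_spec"
  )
}

#' @rdname filter_spec
#' @param name preset name.
#' @export
filter_preset <- function(name = c("proteome_anova", "phospho_ttest", "ecm_ttest")) {
  switch(match.arg(name),
    proteome_anova = filter_spec(0.05, 3, test = "anova"),
    phospho_ttest = filter_spec(0.2, 2, test = "student_t"),
    ecm_ttest = filter_spec(0.1, 1, test = "student_t")
  )
}

#' Apply a significance / fold-change filter
#'
#' Keeps features passing both the significance threshold (BH q for t-test
#' specs; raw ANOVA p for ANOVA specs, matching how the two assays were
#' filtered) and the minimum absolute fold change.
#'
#' @param result a `differential_result`.
#' @param spec a [filter_spec] (or preset name).
#' @return The surviving rows as a tibble; attribute `n_survivors`.
#' @export
apply_filter <- function(result, spec) {
  if (is.character(spec)) spec <- filter_preset(spec)
  stopifnot(inherits(spec, "filter_spec"))
  if (!is.null(attr(result, "test")) && attr(result, "test") != spec$test) {
    abort(sprintf(
      "filter_spec for '%s' applied to a '%s' result",
      spec$test, attr(result, "test")
    ))
  }
  crit <- if (spec$test == "anova") result$p else result$q
  keep <- !is.na(crit) & crit < spec$max_q &
    !is.na(result$log2fc) & abs(result$log2fc) >= log2(spec$min_abs_fold)
  out <- as_tibble(result)[keep, ]
  attr(out, "n_survivors") <- sum(keep)
  out
}

#' Summarize peptides to protein-level profiles
#'
#' Each peptide row is mean-centered across its present values, then each
#' protein/sample entry is the median over that protein's centered peptides
#' (midpoint for even counts) — the "median of mean-centered peptide values"
#' summarization used for relative protein expression heatmaps. Invariant
#' under peptide duplication. Single-peptide proteins pass through centered.
#'
#' @param table a log2-scale [quant_table] whose rows are peptides.
#' @return A protein-level [quant_table] (feature_id = protein_id).
#' @export
protein_summarize <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (table$scale != "log2") abort("protein_summarize requires log2 scale")
  centered <- table$values - rowMeans(table$values, na.rm = TRUE)
  prot <- sort(unique(table$features$protein_id))
  out <- matrix(NA_real_, length(prot), ncol(centered))
  for (i in seq_along(prot)) {
    M <- centered[table$features$protein_id == prot[i], , drop = FALSE]
    out[i, ] <- apply(M, 2, median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  quant_table(
    out,
    features = tibble(feature_id = prot, protein_id = prot),
    samples = table$samples, scale = "log2"
  )
}

#' Collapse per-site scores to one score per protein
#'
#' Retains, for each protein, the site whose score has the largest absolute
#' value (sign preserved). Exact-magnitude ties prefer the positive score,
#' then the lexicographically smallest site label; ties are recorded.
#'
#' @param scores data frame with columns `protein_id`, `feature_id` (or
#'   `site_label`) and `score`.
#' @return Tibble with columns `protein_id`, `score`, `feature_id`
#'   (provenance: the carrying site), `tie`; one row per protein.
#' @export
collapse_to_protein <- function(scores) {
  scores <- as_tibble(scores)
  if (!"feature_id" %in% names(scores)) scores$feature_id <- scores$site_label
  if (any(is.na(scores$score))) abort("collapse_to_protein: NA scores")
  if (!nrow(scores)) abort("no scored sites")
  ord <- order(
    scores$protein_id, -abs(scores$score), -sign(scores$score),
    scores$feature_id,
    method = "radix"
  )
  srt <- scores[ord, ]
  first <- !duplicated(srt$protein_id)
  out <- srt[first, c("protein_id", "score", "feature_id")]
  # a tie: another site of the same protein with the same |score|
  key <- paste(srt$protein_id, abs(srt$score))
  tied_keys <- unique(key[duplicated(key)])
  out$tie <- paste(out$protein_id, abs(out$score)) %in% tied_keys
  out
}

#' Rank features by the signed t statistic
#'
#' Orders a differential result by `sign(log2fc) * |stat|` descending — the
#' "signed t-test of differential expression" ordering used for expression
#' heatmaps and enrichment inputs.
#'
#' @param result a `differential_result`.
#' @return A [rank_features()] ranked list over `feature_id`.
#' @export
signed_t_order <- function(result) {
  ok <- is.finite(result$stat) & !is.na(result$log2fc)
  sc <- sign(result$log2fc[ok]) * abs(result$stat[ok])
  rank_features(tibble(id = result$feature_id[ok], score = sc))
}

#' Rank features by summed fold change across contrasts
#'
#' Per-feature sum of log2 fold changes over two or more differential
#' results (e.g. the two RTK-mechanism resistant/parental pairs), ranked
#' descending — the "sum fold change difference" signature ordering.
#'
#' @param results list of `differential_result` tibbles.
#' @param universe `"intersection"` (default) or `"union"`; union sums over
#'   present contrasts and flags partial coverage in the `n_present` tie
#'   record.
#' @return A `ranked_list` over `feature_id`.
#' @export
sum_fold_change_signature <- function(results, universe = c("intersection", "union")) {
  universe <- match.arg(universe)
  if (length(results) < 1) abort("need at least one differential result")
  fcs <- lapply(results, function(r) {
    r <- as_tibble(r)
    r[!is.na(r$log2fc), c("feature_id", "log2fc")]
  })
  ids <- Reduce(
    if (universe == "intersection") intersect else union,
    lapply(fcs, `[[`, "feature_id")
  )
  if (!length(ids)) abort("empty feature universe across contrasts")
  total <- setNames(numeric(length(ids)), ids)
  for (fc in fcs) {
    hit <- fc$feature_id %in% ids
    total[fc$feature_id[hit]] <- total[fc$feature_id[hit]] + fc$log2fc[hit]
  }
  rank_features(tibble(id = ids, score = unname(total[ids])))
}
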
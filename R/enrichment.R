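# --- permutation internals ------------------------------------------------

# B x m matrix of member positions drawn without replacement from 1..N
sample_positions <- function(B, N, m) {
  t(vapply(seq_len(B), function(i) sample.int(N, m), integer(m)))
}

# sort each row ascending
row_sort <- function(mat) {
  if (ncol(mat) == 1) return(mat)
  o <- order(row(mat), mat, method = "radix")
  matrix(mat[o], nrow = nrow(mat), byrow = TRUE)
}

# classic one-sided KS enrichment statistic for each row of a sorted
# positions matrix: D = max_j (j/m - pos_j/N)
ks_stat_rows <- function(pos_sorted, N) {
  m <- ncol(pos_sorted)
  dev <- sweep(-pos_sorted / N, 2, seq_len(m) / m, `+`)
  do.call(pmax, as.data.frame(dev))
}

# GSEA running-sum extremum for each row of a sorted positions matrix.
# score: the full ranked score vector; weight >= 0 (0 = classic KS walk).
# Returns list(es, argmax) where argmax is the hit index at the extremum.
es_stat_rows <- function(pos_sorted, score, weight, N) {
  B <- nrow(pos_sorted)
  m <- ncol(pos_sorted)
  jmat <- matrix(seq_len(m), B, m, byrow = TRUE)
  miss <- (pos_sorted - jmat) / (N - m)
  if (weight == 0) {
    cw <- jmat
    nr <- rep(m, B)
    w <- matrix(1, B, m)
  } else {
    w <- abs(matrix(score[pos_sorted], B, m))^weight
    cw <- if (m == 1) w else t(apply(w, 1, cumsum))
    nr <- cw[, m]
    nr[nr == 0] <- 1 # all-zero scores in set: walk is pure miss penalty
  }
  high <- cw / nr - miss
  low <- (cw - w) / nr - miss
  hi <- do.call(pmax, as.data.frame(high))
  lo <- do.call(pmin, as.data.frame(low))
  es <- ifelse(hi >= -lo, hi, lo)
  argmax <- ifelse(
    hi >= -lo,
    max.col(high, ties.method = "first"),
    max.col(-low, ties.method = "first")
  )
  list(es = es, argmax = argmax)
}

enrichment_tibble <- function(df, B, seed, statistic) {
  structure(df,
    B = B, seed = seed, statistic = statistic,
    class = c("enrichment_result", class(tibble()))
  )
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    statistic = attr(x, "statistic"), n_sets = nrow(x),
    B = attr(x, "B"), seed = attr(x, "seed")
  )
}

# --- user-facing operations -----------------------------------------------

#' Permutation Kolmogorov-Smirnov rank enrichment test
#'
#' One-sided KS statistic for over-representation of a signature at the top
#' of a ranked list: `D = max over positions of (signature ECDF - uniform
#' background ECDF)`. Significance by gene-label permutation: `B` random
#' draws of the member positions without replacement, add-one estimator
#' `p = (#{D* >= D} + 1) / (B + 1)`. Deterministic given `seed`.
#'
#' @param ranked a `ranked_list` (see [rank_features()]).
#' @param geneset character vector of member identifiers (or a single-set
#'   [gene_sets]).
#' @param B number of permutations (>= 99).
#' @param seed integer seed.
#' @param alternative `"top"` (enrichment among high scores, default) or
#'   `"bottom"` (the list is reversed first).
#' @return One-row `enrichment_result` tibble: `set_name`, `stat` (D),
#'   `NES` (NA), `p`, `q` (NA), `size`, `leading_edge` (list), `flag`.
#' @export
#' @examples
#' rl <- rank_features(setNames(20:1, paste0("g", 1:20)))
#' ks_permutation_test(rl, paste0("g", 1:5), B = 199, seed = 1)
ks_permutation_test <- function(ranked, geneset, B = 10000, seed = 1,
                                alternative = c("top", "bottom")) {
  alternative <- match.arg(alternative)
  if (B < 99) abort("B must be >= 99")
  if (inherits(geneset, "gene_sets")) {
    stopifnot(length(geneset) == 1)
    set_name <- names(geneset)
    geneset <- geneset[[1]]
  } else {
    set_name <- "geneset"
  }
  ids <- ranked$id
  if (alternative == "bottom") ids <- rev(ids)
  N <- length(ids)
  members <- intersect(geneset, ids)
  m <- length(members)
  if (m == 0) abort("geneset does not intersect the ranked universe")
  if (m == N) {
    out <- tibble(
      set_name = set_name, stat = 0, NES = NA_real_, p = 1, q = NA_real_,
      size = m, leading_edge = list(character()), flag = "set_equals_universe"
    )
    return(enrichment_tibble(out, B, seed, "D"))
  }
  pos <- sort(match(members, ids))
  D <- max(seq_len(m) / m - pos / N)
  j_star <- which.max(seq_len(m) / m - pos / N)
  leading <- ids[pos[seq_len(j_star)]]

  set.seed(seed)
  perm <- row_sort(sample_positions(B, N, m))
  D_star <- ks_stat_rows(perm, N)
  p <- (sum(D_star >= D) + 1) / (B + 1)
  out <- tibble(
    set_name = set_name, stat = D, NES = NA_real_, p = p, q = NA_real_,
    size = m, leading_edge = list(leading), flag = ""
  )
  enrichment_tibble(out, B, seed, "D")
}

#' GSEA-style running-sum enrichment with normalized scores
#'
#' Weighted running-sum enrichment score per set (hits increment by
#' `|score|^weight / NR`, misses decrement by `1/(N - m)`; ES is the maximal
#' deviation from zero), with gene-label permutation significance,
#' NES = ES / mean(|ES*| of same-sign permutations), BH q across sets, and
#' leading edge = members at or before the ES extremum. `weight = 0` is the
#' classic unweighted KS walk, `weight = 1` score-weighted.
#'
#' @param ranked a `ranked_list` with scores.
#' @param sets a [gene_sets] collection (or named list).
#' @param B permutations per set.
#' @param seed integer seed.
#' @param weight running-sum weight exponent (>= 0).
#' @param min_size sets smaller than this (after intersection with the
#'   universe) are skipped with a record (attribute `skipped`).
#' @return An `enrichment_result` tibble, one row per tested set, with
#'   columns `set_name`, `stat` (ES), `NES`, `p`, `q`, `size`,
#'   `leading_edge`, `flag`.
#' @export
gsea_es_nes <- function(ranked, sets, B = 1000, seed = 1, weight = 1,
                        min_size = 3) {
  if (weight < 0) abort("weight must be >= 0")
  if (!inherits(sets, "gene_sets")) sets <- gene_sets(sets)
  ids <- ranked$id
  score <- ranked$score
  N <- length(ids)
  set.seed(seed)
  skipped <- character()
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], ids)
    m <- length(members)
    if (m < min_size || m >= N) {
      skipped <- c(skipped, nm)
      next
    }
    pos <- matrix(sort(match(members, ids)), nrow = 1)
    obs <- es_stat_rows(pos, score, weight, N)
    perm <- row_sort(sample_positions(B, N, m))
    es_star <- es_stat_rows(perm, score, weight, N)$es
    same <- if (obs$es >= 0) es_star[es_star >= 0] else es_star[es_star < 0]
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    p <- (sum(abs(same) >= abs(obs$es)) + 1) / (length(same) + 1)
    leading <- if (obs$es >= 0) {
      ids[pos[1, seq_len(obs$argmax)]]
    } else {
      ids[pos[1, seq(obs$argmax, m)]]
    }
    rows[[nm]] <- tibble(
      set_name = nm, stat = obs$es, NES = nes, p = p, q = NA_real_,
      size = m, leading_edge = list(leading), flag = ""
    )
  }
  if (!length(rows)) abort("no testable sets (all skipped)")
  out <- dplyr::bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- enrichment_tibble(out, B, seed, "ES")
  attr(out, "skipped") <- skipped
  out
}

#' Case/control specificity filter on enrichment results
#'
#' Retains sets significantly enriched in every case collection
#' (`q < q_case`) but not in the control collection (`q > q_control`) — the
#' pattern used to call programs specific to the RTK-mechanism lines and
#' absent from the NRAS-mechanism control line. Output is ordered by the
#' summed NES across the case collections.
#'
#' @param case_results list of >= 2 `enrichment_result` tibbles.
#' @param control_results one `enrichment_result` tibble.
#' @param q_case,q_control thresholds.
#' @return Tibble with `set_name`, per-case NES columns, `sum_NES`, ordered
#'   by `sum_NES` descending; attribute `excluded` lists sets missing from
#'   any collection.
#' @export
specificity_filter <- function(case_results, control_results,
                               q_case = 0.1, q_control = 0.2) {
  if (length(case_results) < 2) abort("need >= 2 case collections")
  all_names <- Reduce(union, c(
    lapply(case_results, `[[`, "set_name"), list(control_results$set_name)
  ))
  common <- Reduce(intersect, c(
    lapply(case_results, `[[`, "set_name"), list(control_results$set_name)
  ))
  excluded <- setdiff(all_names, common)
  keep <- common
  nes <- matrix(NA_real_, length(common), length(case_results))
  for (i in seq_along(case_results)) {
    r <- case_results[[i]]
    idx <- match(common, r$set_name)
    qk <- r$q[idx][match(keep, common)]
    keep <- keep[!is.na(qk) & qk < q_case]
    nes[, i] <- r$NES[idx]
  }
  ctrl_q <- control_results$q[match(common, control_results$set_name)]
  qc <- ctrl_q[match(keep, common)]
  keep <- keep[!is.na(qc) & qc > q_control]
  out <- tibble(set_name = keep)
  sel <- match(keep, common)
  for (i in seq_along(case_results)) {
    out[[paste0("NES_case", i)]] <- nes[sel, i]
  }
  out$sum_NES <- rowSums(nes[sel, , drop = FALSE])
  out <- out[order(-out$sum_NES), ]
  attr(out, "excluded") <- excluded
  out
}

#' Kinase-substrate enrichment from a differential phospho profile
#'
#' Ranks phospho-features by their (mean) log2 fold change across the given
#' contrasts and runs [gsea_es_nes()] against kinase-substrate sets
#' (substrates referenced by phospho-feature identifier), flagging kinases
#' passing the BH FDR threshold.
#'
#' @param diff a `differential_result`, or a list of them (fold changes are
#'   averaged over the shared feature universe).
#' @param substrate_sets [gene_sets] keyed by kinase, members =
#'   phospho-feature identifiers.
#' @param B,seed,weight,min_size passed to [gsea_es_nes()].
#' @param q_max FDR threshold for the `significant` column.
#' @param direction `"up"` (default): only positive-NES kinases (upregulated
#'   activities) are called significant; `"both"` ignores the sign. The
#'   one-sided default guards against depletion artifacts of gene-label
#'   permutation when strong programs occupy the top of the ranking.
#' @return An `enrichment_result` tibble with an extra `significant` column.
#' @export
kinase_enrichment <- function(diff, substrate_sets, B = 1000, seed = 1,
                              weight = 1, min_size = 3, q_max = 0.2,
                              direction = c("up", "both")) {
  direction <- match.arg(direction)
  if (inherits(diff, "differential_result")) diff <- list(diff)
  fcs <- lapply(diff, function(r) {
    r <- as_tibble(r)
    r[!is.na(r$log2fc), c("feature_id", "log2fc")]
  })
  ids <- Reduce(intersect, lapply(fcs, `[[`, "feature_id"))
  if (!length(ids)) abort("empty phospho universe")
  mean_fc <- rowMeans(vapply(
    fcs, function(fc) fc$log2fc[match(ids, fc$feature_id)],
    numeric(length(ids))
  ))
  ranked <- rank_features(tibble(id = ids, score = mean_fc))
  out <- gsea_es_nes(ranked, substrate_sets,
    B = B, seed = seed,
    weight = weight, min_size = min_size
  )
  out$significant <- out$q < q_max &
    (direction == "both" | out$NES > 0)
  out
}

#' Test a directed signature at both ends of a ranking
#'
#' For an up/down-labelled signature pair (e.g. invasive-up /
#' proliferative-down phenotype genes), runs [ks_permutation_test()] for the
#' up set at the top and the down set at the bottom of the ranked list and
#' reports both jointly.
#'
#' @param ranked a `ranked_list`.
#' @param sets a [gene_sets] with direction labels `"up"`/`"down"`.
#' @param B,seed passed to [ks_permutation_test()].
#' @return An `enrichment_result` tibble with one row per directed set and
#'   an `end` column (`"top"`/`"bottom"`).
#' @export
directed_signature_test <- function(ranked, sets, B = 10000, seed = 1) {
  stopifnot(inherits(sets, "gene_sets"))
  dirs <- attr(sets, "direction")
  rows <- list()
  for (nm in names(sets)) {
    if (dirs[[nm]] == "undirected") next
    end <- if (dirs[[nm]] == "up") "top" else "bottom"
    r <- ks_permutation_test(ranked, sets[nm], B = B, seed = seed, alternative = end)
    r$end <- end
    rows[[nm]] <- r
  }
  if (!length(rows)) abort("no directed sets in the collection")
  out <- dplyr::bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  enrichment_tibble(out, B, seed, "D")
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- as_tibble(object)
  df$value <- if (all(is.na(df$NES))) df$stat else df$NES
  df <- df[order(df$value), ]
  df$set_name <- factor(df$set_name, levels = df$set_name)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$set_name, fill = .data$q < 0.2)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = if (all(is.na(df$NES))) "KS D" else "NES", y = NULL,
      fill = "q < 0.2"
    ) +
    ggplot2::theme_minimal()
}
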
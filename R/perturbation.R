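#' Combined perturbation score across adaptation-state contrasts
#'
#' The headline ranking statistic for signaling alterations shared between
#' contrasts (e.g. the two resistant/parental and the two
#' persistent/parental pairs): per phospho-site, the sum `S` of the signed
#' log-t scores `s = sign(log2fc) * (-log10 p)` over the contrasts (each
#' capped at +/-300), then collapsed to one site per protein by largest
#' absolute sum ([collapse_to_protein()]). Shared-up and shared-down
#' candidates are reported as two rank columns rather than one
#' absolute-value list, since candidate targets are directional.
#'
#' Sites missing from some contrasts are handled per `coverage_policy`:
#' `"allow_missing"` (default) sums over the present contrasts, flags the
#' site (`n_contrasts_present` < total) and breaks score ties in favor of
#' better coverage, so a partially observed site never outranks a fully
#' observed site with the same per-contrast scores; `"require_all"` keeps
#' only sites tested in every contrast.
#'
#' @param diffs list of >= 2 `differential_result` tibbles.
#' @param coverage_policy `"allow_missing"` or `"require_all"`.
#' @param cap cap on each per-contrast |s|.
#' @return A tibble of class `perturbation_scores`: `protein_id`,
#'   `feature_id` (the carrying site), `site_label`, one `s_<contrast>`
#'   column per contrast, `S`, `n_contrasts_present`, `coverage_flag`,
#'   `rank_up`, `rank_down`, `tie`.
#' @export
combined_perturbation_score <- function(diffs,
                                        coverage_policy = c("allow_missing", "require_all"),
                                        cap = 300) {
  coverage_policy <- match.arg(coverage_policy)
  if (length(diffs) < 2) abort("need >= 2 contrasts")
  nms <- vapply(seq_along(diffs), function(i) {
    attr(diffs[[i]], "contrast") %||% paste0("contrast", i)
  }, character(1))
  if (anyDuplicated(nms)) nms <- make.unique(nms)

  per <- lapply(seq_along(diffs), function(i) {
    r <- as_tibble(diffs[[i]])
    r <- r[!is.na(r$s), c("feature_id", "protein_id", "site_label", "s")]
    r$s <- pmin(pmax(r$s, -cap), cap)
    names(r)[names(r) == "s"] <- paste0("s_", nms[i])
    r
  })
  merged <- Reduce(function(x, y) {
    dplyr::full_join(x, y, by = c("feature_id", "protein_id", "site_label"))
  }, per)
  s_cols <- paste0("s_", nms)
  S_mat <- as.matrix(merged[s_cols])
  merged$n_contrasts_present <- as.integer(rowSums(!is.na(S_mat)))
  if (coverage_policy == "require_all") {
    merged <- merged[merged$n_contrasts_present == length(diffs), ]
    if (!nrow(merged)) abort("no sites tested in every contrast")
    S_mat <- as.matrix(merged[s_cols])
  }
  merged$S <- rowSums(S_mat, na.rm = TRUE)
  merged$coverage_flag <- merged$n_contrasts_present < length(diffs)

  # collapse to one site per protein by largest |S|
  col <- collapse_to_protein(tibble(
    protein_id = merged$protein_id, feature_id = merged$feature_id,
    score = merged$S
  ))
  out <- merged[match(
    paste(col$protein_id, col$feature_id),
    paste(merged$protein_id, merged$feature_id)
  ), ]
  out$tie <- col$tie

  # rank: shared-up descending S, shared-down ascending; ties favor coverage
  out$rank_up <- out$rank_down <- NA_integer_
  ord_up <- order(-out$S, -out$n_contrasts_present, out$protein_id, method = "radix")
  ord_dn <- order(out$S, -out$n_contrasts_present, out$protein_id, method = "radix")
  out$rank_up[ord_up] <- seq_len(nrow(out))
  out$rank_down[ord_dn] <- seq_len(nrow(out))
  out <- out[order(out$rank_up), ]
  structure(out,
    contrasts = nms, coverage_policy = coverage_policy,
    class = c("perturbation_scores", class(tibble()))
  )
}

#' @export
glance.perturbation_scores <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    n_contrasts = length(attr(x, "contrasts")),
    coverage_policy = attr(x, "coverage_policy"),
    n_partial_coverage = sum(x$coverage_flag)
  )
}

#' @export
autoplot.perturbation_scores <- function(object, top_n = 20, ...) {
  df <- utils::head(as_tibble(object)[order(object$rank_up), ], top_n)
  df$protein_id <- factor(df$protein_id, levels = rev(df$protein_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$S, .data$protein_id, fill = .data$coverage_flag)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "combined perturbation score S", y = NULL,
      fill = "partial coverage"
    ) +
    ggplot2::theme_minimal()
}

#' Planted-target recovery from a perturbation ranking
#'
#' Validation harness for synthetic runs: the fraction of planted shared-up
#' (or shared-down) proteins found in the top `k` of the combined
#' perturbation ranking.
#'
#' @param table a `perturbation_scores` tibble.
#' @param truth ground truth from [simulate_experiment()] (the `truth`
#'   element), or a character vector of planted protein ids.
#' @param k top-list size (`k <= nrow(table)`).
#' @param direction `"up"` (uses `rank_up`) or `"down"`.
#' @param program which planted program to score when `truth` is a truth
#'   object.
#' @return The recovery fraction (numeric scalar).
#' @export
recover_shared_targets <- function(table, truth, k, direction = c("up", "down"),
                                   program = "shared_up") {
  direction <- match.arg(direction)
  if (k > nrow(table)) abort("k exceeds the number of ranked proteins")
  planted <- if (is.character(truth)) truth else truth$programs[[program]]
  if (is.null(planted) || !length(planted)) abort("no planted proteins in truth")
  rk <- if (direction == "up") table$rank_up else table$rank_down
  top <- table$protein_id[rk <= k]
  mean(planted %in% top)
}
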
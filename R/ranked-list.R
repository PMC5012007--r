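#' Rank identifiers by score
#'
#' Produces a strictly ordered ranked list (descending by score) from a
#' score table, the carrier for fold-change orderings and signed-statistic
#' orderings. Ties are broken deterministically and recorded.
#'
#' @param scores a data frame with columns `id` and `score`, or a named
#'   numeric vector.
#' @param tie_rule `"lexicographic"` (default: ties ordered by identifier) or
#'   `"input"` (ties keep input order).
#' @return A tibble of class `ranked_list` with columns `id`, `score`, `rank`;
#'   attribute `ties` records tied score groups.
#' @export
#' @examples
#' rank_features(c(a = 2, b = 1, c = 3))$id
rank_features <- function(scores, tie_rule = c("lexicographic", "input")) {
  tie_rule <- match.arg(tie_rule)
  if (is.numeric(scores)) {
    if (is.null(names(scores))) abort("numeric scores must be named")
    scores <- tibble(id = names(scores), score = unname(scores))
  }
  scores <- as_tibble(scores)[c("id", "score")]
  if (anyDuplicated(scores$id)) abort("identifiers must be unique")
  if (any(!is.finite(scores$score))) abort("scores must be finite (no NaN/Inf/NA)")
  ord <- if (tie_rule == "lexicographic") {
    order(-scores$score, scores$id, method = "radix")
  } else {
    order(-scores$score, method = "radix")
  }
  out <- scores[ord, ]
  out$rank <- seq_len(nrow(out))
  tied <- out$score %in% out$score[duplicated(out$score)]
  ties <- dplyr::group_by(out[tied, c("id", "score")], .data$score)
  structure(
    out,
    ties = dplyr::summarise(ties, ids = list(.data$id), .groups = "drop"),
    tie_rule = tie_rule,
    class = c("ranked_list", class(tibble())))
}

#' Read / write RNK files
#'
#' RNK: two tab-separated columns, identifier and real-valued score, no
#' header. Reading re-ranks with [rank_features()].
#'
#' @param path file path.
#' @param tie_rule passed to [rank_features()].
#' @return `read_rnk()`: a `ranked_list` tibble. `write_rnk()`: input, invisibly.
#' @export
read_rnk <- function(path, tie_rule = "lexicographic") {
  df <- readr::read_tsv(path,
    col_names = c("id", "score"),
    col_types = readr::cols(id = "c", score = "d")
  )
  rank_features(df, tie_rule = tie_rule)
}

#' @rdname read_rnk
#' @param ranked a `ranked_list` (or any id/score data frame) to write.
#' @export
write_rnk <- function(ranked, path) {
  readr::write_tsv(as_tibble(ranked)[c("id", "score")], path, col_names = FALSE)
  invisible(ranked)
}
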
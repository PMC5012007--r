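#' Cross-tabulate direction of change between two contrasts
#'
#' Builds the 2x2 table of up/down direction agreement for features that are
#' significantly altered in either (default) or both contrasts, the input to
#' the direction-concordance exact test. Zero-fold-change features cannot be
#' assigned a direction and are excluded with a count.
#'
#' @param diffA,diffB `differential_result` tibbles sharing features.
#' @param sig_policy `"either"` (significant in at least one contrast,
#'   default) or `"both"`.
#' @param alpha significance threshold.
#' @param criterion `"q"` (BH FDR, default) or `"p"`.
#' @return A 2x2 integer matrix of class `direction_table` (rows: up/down in
#'   A; columns: up/down in B), with attributes `policy`, `alpha`,
#'   `n_zero_excluded`, `n_shared`.
#' @export
build_direction_table <- function(diffA, diffB, sig_policy = c("either", "both"),
                                  alpha = 0.05, criterion = c("q", "p")) {
  sig_policy <- match.arg(sig_policy)
  criterion <- match.arg(criterion)
  a <- as_tibble(diffA)[c("feature_id", "log2fc", criterion)]
  b <- as_tibble(diffB)[c("feature_id", "log2fc", criterion)]
  names(a) <- c("feature_id", "fc_a", "crit_a")
  names(b) <- c("feature_id", "fc_b", "crit_b")
  m <- dplyr::inner_join(a, b, by = "feature_id")
  m <- m[stats::complete.cases(m), ]
  if (!nrow(m)) abort("no shared tested features between the contrasts")
  sig_a <- m$crit_a < alpha
  sig_b <- m$crit_b < alpha
  sig <- if (sig_policy == "either") sig_a | sig_b else sig_a & sig_b
  zero <- m$fc_a == 0 | m$fc_b == 0
  keep <- sig & !zero
  if (!any(keep)) abort("no qualifying features for the direction table")
  tab <- table(
    factor(ifelse(m$fc_a[keep] > 0, "up", "down"), levels = c("up", "down")),
    factor(ifelse(m$fc_b[keep] > 0, "up", "down"), levels = c("up", "down"))
  )
  structure(
    matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab)),
    policy = sig_policy, alpha = alpha,
    n_zero_excluded = sum(sig & zero), n_shared = nrow(m),
    class = "direction_table"
  )
}

#' @export
print.direction_table <- function(x, ...) {
  cat(sprintf(
    "<direction_table> policy=%s alpha=%g (zero-fold excluded: %d)\n",
    attr(x, "policy"), attr(x, "alpha"), attr(x, "n_zero_excluded")
  ))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Fisher's exact test on a 2x2 direction table
#'
#' Exact two-sided p-value for association in a 2x2 table, by summing the
#' hypergeometric probabilities (at fixed margins) of all tables no more
#' probable than the observed one (the minimum-likelihood convention).
#'
#' @param table 2x2 integer matrix (e.g. a `direction_table`).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The p-value (numeric scalar).
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
fisher_exact_2x2 <- function(table, alternative = "two.sided") {
  m <- matrix(as.numeric(unclass(table)), 2, 2)
  if (any(m < 0) || any(m != round(m))) abort("table must hold non-negative counts")
  if (sum(m) < 1) abort("all-zero table")
  fisher.test(m, alternative = alternative)$p.value
}
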
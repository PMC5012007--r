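#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — drawing `n` items from a
#' universe of `N` containing `K` marked ones — computed in log space. The
#' cell statistic of the rank-rank hypergeometric overlap map.
#'
#' @param N universe size.
#' @param K number of marked items.
#' @param n draw size.
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @return The tail probability (numeric, vectorized over its arguments).
#' @export
#' @examples
#' hypergeometric_tail(10, 5, 5, 5) # 1/choose(10, 5)
hypergeometric_tail <- function(N, K, n, k) {
  if (any(K > N | n > N | k > pmin(K, n) | k < 0 | K < 0 | n < 0)) {
    abort("inconsistent hypergeometric parameters")
  }
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

# lower tail P(X <= k), for signed (depletion) maps
hypergeometric_lower <- function(N, K, n, k) {
  exp(phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
}

#' Rank-rank hypergeometric overlap map
#'
#' Measures agreement between two ranked lists over a grid of rank
#' thresholds: for each threshold pair `(i, j)` the overlap
#' `k = |top-i of A  /\  top-j of B|` is scored by the hypergeometric tail
#' `P(X >= k)` with `X ~ Hypergeometric(N, i, j)`, reported as `-log10 p`.
#' The universe is the intersection of the two lists' identifiers (discarded
#' identifiers are recorded). Optional BH/BY correction across all cells;
#' optional signed map (negative values mark significant depletion via the
#' lower tail).
#'
#' @param listA,listB `ranked_list` tibbles (see [rank_features()]).
#' @param step rank-threshold step size; default `max(1, floor(N / 100))`.
#' @param correction `"none"` (default), `"BH"` or `"BY"`, applied across all
#'   cells.
#' @param signed if `TRUE`, cells where the depletion tail is the smaller
#'   p-value are reported as `+log10 p_depletion` (i.e. negative map value).
#' @return A list of class `rrho_map`: `map` (matrix of signed -log10 p),
#'   `p` (raw enrichment-tail p matrix), `k` (overlap counts),
#'   `thresholds_a`, `thresholds_b`, `N`, `correction`, `n_discarded`,
#'   `summary` (max value and its threshold location).
#' @export
rrho_map <- function(listA, listB, step = NULL,
                     correction = c("none", "BH", "BY"), signed = FALSE) {
  correction <- match.arg(correction)
  ids <- intersect(listA$id, listB$id)
  N <- length(ids)
  if (N == 0) abort("the two lists share no identifiers")
  n_discarded <- length(listA$id) + length(listB$id) - 2 * N
  step <- step %||% max(1L, floor(N / 100))
  if (step > N) abort("step exceeds the universe size")
  # re-rank within the shared universe, preserving each list's order
  ra <- rank(match(ids, listA$id))
  rb <- rank(match(ids, listB$id))
  thr <- unique(c(seq(step, N, by = step), N))

  Ai <- vapply(thr, function(t) ra <= t, logical(N))
  Bj <- vapply(thr, function(t) rb <= t, logical(N))
  k <- crossprod(Ai, Bj) # overlap counts, |thr| x |thr|

  Kmat <- matrix(thr, length(thr), length(thr))
  nmat <- t(Kmat)
  p_enrich <- matrix(
    hypergeometric_tail(N, as.vector(Kmat), as.vector(nmat), as.vector(k)),
    length(thr), length(thr)
  )
  adjust <- function(p) {
    if (correction == "none") return(p)
    matrix(p.adjust(as.vector(p), method = correction), nrow(p), ncol(p))
  }
  map <- -log10(pmax(adjust(p_enrich), .Machine$double.xmin))
  if (signed) {
    p_dep <- matrix(
      hypergeometric_lower(N, as.vector(Kmat), as.vector(nmat), as.vector(k)),
      length(thr), length(thr)
    )
    dep <- adjust(p_dep)
    neg <- p_dep < p_enrich
    map[neg] <- log10(pmax(dep[neg], .Machine$double.xmin))
  }
  imax <- arrayInd(which.max(map), dim(map))
  structure(
    list(
      map = map, p = p_enrich, k = k,
      thresholds_a = thr, thresholds_b = thr, N = N,
      correction = correction, signed = signed, n_discarded = n_discarded,
      summary = list(
        max = max(map),
        at = c(rank_a = thr[imax[1]], rank_b = thr[imax[2]])
      )
    ),
    class = "rrho_map"
  )
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf(
    "<rrho_map> %dx%d cells, N=%d, correction=%s; max -log10 p = %.2f at (%d, %d)\n",
    nrow(x$map), ncol(x$map), x$N, x$correction,
    x$summary$max, x$summary$at[1], x$summary$at[2]
  ))
  invisible(x)
}

#' @export
tidy.rrho_map <- function(x, ...) {
  tibble(
    rank_a = rep(x$thresholds_a, each = length(x$thresholds_b)),
    rank_b = rep(x$thresholds_b, times = length(x$thresholds_a)),
    overlap = as.vector(t(x$k)),
    p = as.vector(t(x$p)),
    neglog10p = as.vector(t(x$map))
  )
}

#' @export
glance.rrho_map <- function(x, ...) {
  tibble(
    N = x$N, n_cells = length(x$map), correction = x$correction,
    max_neglog10p = x$summary$max,
    at_rank_a = unname(x$summary$at[1]), at_rank_b = unname(x$summary$at[2]),
    n_discarded = x$n_discarded
  )
}

#' @export
autoplot.rrho_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank_a, .data$rank_b, fill = .data$neglog10p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = "rank threshold, list A", y = "rank threshold, list B") +
    ggplot2::theme_minimal()
}

#' Write an RRHO map to plain-text files
#'
#' @param x an `rrho_map`.
#' @param matrix_path TSV destination for the -log10 p matrix.
#' @param summary_path optional JSON destination for [glance()] output.
#' @return `x`, invisibly.
#' @export
write_rrho <- function(x, matrix_path, summary_path = NULL) {
  m <- as.data.frame(x$map)
  names(m) <- paste0("b", x$thresholds_b)
  m <- cbind(rank_a = x$thresholds_a, m)
  readr::write_tsv(as_tibble(m), matrix_path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(as.list(glance(x)), summary_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(x)
}
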
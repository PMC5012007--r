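# -- tiny quantification-table builders ------------------------------------

# one cell line, two states, arbitrary replicate counts
two_group_qt <- function(a, b, n_features = 1) {
  vals <- rbind(matrix(c(a, b), nrow = 1))
  if (n_features > 1) vals <- vals[rep(1, n_features), , drop = FALSE]
  samples <- data.frame(
    sample = c(paste0("a", seq_along(a)), paste0("b", seq_along(b))),
    cell_line = "cl",
    state = rep(c("parental", "resistant"), c(length(a), length(b))),
    replicate = c(seq_along(a), seq_along(b))
  )
  quant_table(
    vals,
    features = data.frame(
      feature_id = paste0("f", seq_len(n_features)),
      protein_id = paste0("P", seq_len(n_features))
    ),
    samples = samples
  )
}

two_group_contrast <- contrast(
  "RvP",
  group_a = list(cell_line = "cl", state = "parental"),
  group_b = list(cell_line = "cl", state = "resistant")
)

# matrix -> quant_table with anova-style labels (uses character groups)
matrix_qt <- function(vals, states = NULL) {
  n <- ncol(vals)
  samples <- data.frame(
    sample = paste0("s", seq_len(n)), cell_line = "cl",
    state = states %||% rep("parental", n), replicate = seq_len(n)
  )
  quant_table(
    vals,
    features = data.frame(
      feature_id = paste0("f", seq_len(nrow(vals))),
      protein_id = paste0("P", seq_len(nrow(vals)))
    ),
    samples = samples
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# mock differential result with the columns downstream ops need
mock_diff <- function(feature_id, log2fc, p = NULL, stat = NULL, q = NULL,
                      protein_id = feature_id, site_label = NA_character_,
                      contrast_name = "mock", test = "student_t") {
  n <- length(feature_id)
  p <- p %||% rep(0.5, n)
  stat <- stat %||% -sign(log2fc) * abs(qt(p / 2, df = 4))
  q <- q %||% p.adjust(p, "BH")
  out <- tibble::tibble(
    feature_id = feature_id, protein_id = protein_id, site_label = site_label,
    log2fc = log2fc, stat = stat, p = p, q = q,
    s = sign(log2fc) * (-log10(p)),
    n_a = 3L, n_b = 3L, flag = ""
  )
  structure(out,
    contrast = contrast_name, test = test,
    class = c("differential_result", class(tibble::tibble()))
  )
}

# -- independent oracles ----------------------------------------------------

# literal Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(pmin(ranked, 1))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# exhaustive two-sided Fisher p at fixed margins (minimum-likelihood rule,
# including the relative tolerance used by the standard implementation)
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  aa <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(aa, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# hypergeometric upper tail by direct summation of the pmf
hyper_tail_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# RRHO cell by explicit set intersection + tail summation
rrho_cell_oracle <- function(idsA, idsB, i, j) {
  k <- length(intersect(idsA[seq_len(i)], idsB[seq_len(j)]))
  hyper_tail_oracle(length(idsA), i, j, k)
}

# brute-force average-linkage agglomeration; returns sorted merge heights
average_linkage_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(D[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}

# classic one-sided KS enrichment statistic, direct ECDF computation
ks_D_oracle <- function(positions, m, N) {
  max(vapply(seq_len(N), function(i) {
    sum(positions <= i) / m - i / N
  }, numeric(1)))
}
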
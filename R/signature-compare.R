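#' Pairwise Pearson correlation of fold-change signatures
#'
#' Correlates named fold-change vectors (signatures) over their
#' pairwise-complete shared identifiers, the basis of the clustered
#' signature-similarity matrix. Pairs sharing fewer than `min_overlap`
#' identifiers are an error; a constant vector within a pair gives an
#' undefined correlation which is flagged `NA` (never silently 0).
#'
#' @param signatures a wide data frame with an `id` column and one numeric
#'   column per signature, or a named list of named numeric vectors.
#' @param min_overlap minimum pairwise-complete identifiers per pair
#'   (default 3; use ~100 for genome-scale comparisons).
#' @return A list of class `signature_matrix`: `r` (correlation matrix,
#'   unit diagonal), `n` (pairwise-complete counts), `signatures` (the wide
#'   tibble used).
#' @export
pairwise_signature_correlation <- function(signatures, min_overlap = 3) {
  if (is.list(signatures) && !is.data.frame(signatures)) {
    ids <- Reduce(union, lapply(signatures, names))
    wide <- tibble(id = ids)
    for (nm in names(signatures)) wide[[nm]] <- unname(signatures[[nm]][match(ids, names(signatures[[nm]]))])
    signatures <- wide
  }
  signatures <- as_tibble(signatures)
  stopifnot("id" %in% names(signatures))
  X <- as.matrix(signatures[setdiff(names(signatures), "id")])
  if (ncol(X) < 2) abort("need >= 2 signatures")
  pres <- !is.na(X)
  n <- crossprod(pres)
  off <- n[upper.tri(n)]
  if (any(off < min_overlap)) {
    abort(sprintf(
      "signature pair(s) share fewer than %d identifiers (min %d)",
      min_overlap, min(off)
    ))
  }
  r <- suppressWarnings(cor(X, use = "pairwise.complete.obs", method = "pearson"))
  diag(r) <- 1
  structure(
    list(r = r, n = n, signatures = signatures, linkage = NULL, leaf_order = NULL),
    class = "signature_matrix"
  )
}

#' Hierarchical clustering of a signature correlation matrix
#'
#' Agglomerative clustering on the distance `1 - r` (not `1 - |r|`:
#' anti-correlated control signatures are meaningfully distant). Average
#' linkage by default. Deterministic given input order.
#'
#' @param matrix a `signature_matrix` with complete `r`.
#' @param linkage_rule `"average"` (default) or `"complete"`.
#' @return The `signature_matrix` with `linkage` (an [stats::hclust] tree)
#'   and `leaf_order` filled in.
#' @export
hierarchical_cluster <- function(matrix, linkage_rule = c("average", "complete")) {
  linkage_rule <- match.arg(linkage_rule)
  stopifnot(inherits(matrix, "signature_matrix"))
  if (any(is.na(matrix$r))) {
    abort("correlation matrix has undefined entries; cannot cluster")
  }
  hc <- hclust(as.dist(1 - matrix$r), method = linkage_rule)
  matrix$linkage <- hc
  matrix$leaf_order <- colnames(matrix$r)[hc$order]
  matrix
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf(
    "<signature_matrix> %d signatures%s\n", ncol(x$r),
    if (is.null(x$linkage)) "" else sprintf(" (clustered: %s linkage)", x$linkage$method)
  ))
  print(round(x$r, 3))
  invisible(x)
}

#' @export
tidy.signature_matrix <- function(x, ...) {
  nm <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    signature_a = nm[idx[, 1]], signature_b = nm[idx[, 2]],
    r = x$r[idx], n = x$n[idx]
  )
}

#' @export
glance.signature_matrix <- function(x, ...) {
  tibble(
    n_signatures = ncol(x$r),
    mean_abs_r = mean(abs(x$r[upper.tri(x$r)])),
    clustered = !is.null(x$linkage),
    linkage = if (is.null(x$linkage)) NA_character_ else x$linkage$method
  )
}

#' @export
autoplot.signature_matrix <- function(object, ...) {
  nm <- colnames(object$r)
  ord <- object$leaf_order %||% nm
  df <- tibble(
    signature_a = factor(rep(nm, times = length(nm)), levels = ord),
    signature_b = factor(rep(nm, each = length(nm)), levels = ord),
    r = as.vector(object$r)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$signature_a, .data$signature_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cut the signature tree into k groups
#'
#' @param matrix a clustered `signature_matrix`.
#' @param k number of groups.
#' @return A tibble with `signature` and `cluster`.
#' @export
cut_signature_tree <- function(matrix, k) {
  stopifnot(inherits(matrix, "signature_matrix"), !is.null(matrix$linkage))
  cl <- cutree(matrix$linkage, k = k)
  tibble(signature = names(cl), cluster = unname(cl))
}
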
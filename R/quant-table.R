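#' Feature-by-sample quantification table
#'
#' `quant_table()` builds the container used throughout the package for
#' label-free quantification data: a numeric matrix of intensities (raw scale)
#' or log2 intensities, one row per quantified feature (phospho-peptide,
#' protein or gene), one column per sample, with an explicit missing-value
#' mask (`NA`) and per-sample annotation. Missing values are never imputed at
#' construction or I/O time; each downstream operation states its own policy.
#'
#' @param values numeric matrix; rownames are ignored (feature identity comes
#'   from `features`). `NA` marks non-detected entries.
#' @param features data frame with columns `feature_id` (unique, one row per
#'   matrix row), `protein_id`, and optionally `site_label` (e.g. `"S63"`).
#' @param samples data frame with columns `sample`, `cell_line`,
#'   `state` (one of `"parental"`, `"persistent"`, `"resistant"`) and
#'   `replicate` (positive integer), one row per matrix column.
#' @param scale `"log2"` or `"raw"`. Raw-scale tables must be non-negative
#'   on present values.
#'
#' @return An object of class `quant_table`: a list with elements `values`,
#'   `features` (tibble), `samples` (tibble) and `scale`.
#' @export
#' @examples
#' qt <- quant_table(
#'   matrix(rnorm(6), 2, 3),
#'   features = data.frame(feature_id = c("f1", "f2"), protein_id = c("P1", "P2")),
#'   samples = data.frame(
#'     sample = c("a1", "a2", "b1"), cell_line = "cellA",
#'     state = c("parental", "parental", "resistant"), replicate = c(1L, 2L, 1L)
#'   )
#' )
#' dim(qt)
quant_table <- function(values, features, samples, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  features <- as_tibble(features)
  samples <- as_tibble(samples)
  if (!"site_label" %in% names(features)) features$site_label <- NA_character_
  need_f <- c("feature_id", "protein_id")
  if (!all(need_f %in% names(features))) {
    abort(paste0("`features` must have columns: ", paste(need_f, collapse = ", ")))
  }
  need_s <- c("sample", "cell_line", "state", "replicate")
  if (!all(need_s %in% names(samples))) {
    abort(paste0("`samples` must have columns: ", paste(need_s, collapse = ", ")))
  }
  if (nrow(features) != nrow(values)) {
    abort("`features` must have one row per matrix row")
  }
  if (nrow(samples) != ncol(values)) {
    abort("`samples` must have one row per matrix column")
  }
  dup <- unique(features$feature_id[duplicated(features$feature_id)])
  if (length(dup)) {
    abort(paste0("duplicated feature_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad_state <- setdiff(unique(samples$state), c("parental", "persistent", "resistant"))
  if (length(bad_state)) {
    abort(paste0("unknown state: ", paste(bad_state, collapse = ", ")))
  }
  if (any(samples$replicate < 1)) abort("`replicate` must be a positive integer")
  if (scale == "raw" && any(values < 0, na.rm = TRUE)) {
    abort("raw-scale table contains negative values")
  }
  rownames(values) <- features$feature_id
  colnames(values) <- samples$sample
  structure(
    list(values = values, features = features, samples = samples, scale = scale),
    class = "quant_table"
  )
}

#' @export
dim.quant_table <- function(x) dim(x$values)

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf(
    "<quant_table> %d features x %d samples (%s scale), %d missing\n",
    nrow(x$values), ncol(x$values), x$scale, sum(is.na(x$values))
  ))
  print(dplyr::count(x$samples, .data$cell_line, .data$state), n = 12)
  invisible(x)
}

#' @describeIn quant_table long-format view: one row per present or missing cell.
#' @param x a `quant_table`
#' @param ... unused
#' @export
as_tibble.quant_table <- function(x, ...) {
  long <- tibble(
    feature_id = rep(x$features$feature_id, times = ncol(x$values)),
    protein_id = rep(x$features$protein_id, times = ncol(x$values)),
    site_label = rep(x$features$site_label, times = ncol(x$values)),
    sample = rep(x$samples$sample, each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample")
}

#' @export
tidy.quant_table <- function(x, ...) as_tibble.quant_table(x)

#' Read / write a quantification table
#'
#' `read_quant_table()` parses a delimited text file whose first column is
#' `feature_id` (optionally followed by `protein_id` and `site_label` columns)
#' and whose remaining header names are sample names; missing values are coded
#' as empty cells or `NA`. Any other non-numeric cell is an error, never a
#' silent `NA`. Sample annotation comes from `meta`, a data frame (or path to
#' a TSV) with columns `sample`, `cell_line`, `state`, `replicate`.
#'
#' @param path file path of a tab-separated table.
#' @param meta sample annotation: data frame or TSV path.
#' @param scale declared scale of the stored values (`"log2"` or `"raw"`).
#' @return `read_quant_table()`: a [quant_table]. `write_quant_table()`: the
#'   input, invisibly.
#' @export
read_quant_table <- function(path, meta, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (is.character(meta)) {
    meta <- readr::read_tsv(meta, col_types = readr::cols(
      sample = "c", cell_line = "c", state = "c", replicate = "i"
    ))
  }
  meta <- as_tibble(meta)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = "c"),
    na = character()
  )
  if (names(raw)[1] != "feature_id") abort("first column must be `feature_id`")
  anno_cols <- intersect(c("protein_id", "site_label"), names(raw))
  sample_cols <- setdiff(names(raw), c("feature_id", anno_cols))
  missing_meta <- setdiff(sample_cols, meta$sample)
  if (length(missing_meta)) {
    abort(paste0(
      "samples in header absent from annotation: ",
      paste(missing_meta, collapse = ", ")
    ))
  }
  dup <- unique(raw$feature_id[duplicated(raw$feature_id)])
  if (length(dup)) {
    abort(paste0("duplicated feature row: ", paste(head(dup, 5), collapse = ", ")))
  }
  parse_col <- function(txt, col) {
    out <- rep(NA_real_, length(txt))
    filled <- !(txt %in% c("", "NA"))
    suppressWarnings(num <- as.numeric(txt[filled]))
    bad <- which(is.na(num))
    if (length(bad)) {
      abort(sprintf(
        "unparseable numeric cell in column '%s': '%s' (feature %s)",
        col, txt[filled][bad[1]], raw$feature_id[filled][bad[1]]
      ))
    }
    out[filled] <- num
    out
  }
  values <- vapply(sample_cols, function(cn) parse_col(raw[[cn]], cn),
    numeric(nrow(raw))
  )
  if (nrow(raw) == 1L) values <- matrix(values, nrow = 1, dimnames = list(NULL, sample_cols))
  na_chr <- function(x) replace(x, x %in% c("", "NA"), NA_character_)
  features <- tibble(
    feature_id = raw$feature_id,
    protein_id = if ("protein_id" %in% anno_cols) na_chr(raw$protein_id) else raw$feature_id,
    site_label = if ("site_label" %in% anno_cols) na_chr(raw$site_label) else NA_character_
  )
  samples <- meta[match(sample_cols, meta$sample), , drop = FALSE]
  quant_table(values, features, samples, scale = scale)
}

#' @rdname read_quant_table
#' @param table a [quant_table] to write.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  out <- dplyr::bind_cols(
    table$features[c("feature_id", "protein_id", "site_label")],
    as_tibble(table$values)
  )
  readr::write_tsv(out, path, na = "NA")
  invisible(table)
}

#' Define a two-group contrast
#'
#' A contrast names two disjoint sample groups by `(cell_line, state)`
#' selectors, in the direction `group_b` vs `group_a` (log2 fold changes are
#' reported as `mean_b - mean_a`, e.g. resistant vs parental).
#'
#' @param name label for the contrast, used in result columns.
#' @param group_a,group_b lists with elements `cell_line` (character vector or
#'   `NULL` for any) and `state`.
#' @return An object of class `contrast`.
#' @export
#' @examples
#' contrast(
#'   "cellA_RvP",
#'   group_a = list(cell_line = "cellA", state = "parental"),
#'   group_b = list(cell_line = "cellA", state = "resistant")
#' )
contrast <- function(name, group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (!is.list(g) || is.null(g$state)) abort("group selectors need a `state`")
  }
  structure(
    list(name = name, group_a = group_a, group_b = group_b, paired = FALSE),
    class = "contrast"
  )
}

#' @export
print.contrast <- function(x, ...) {
  fmt <- function(g) {
    paste0(
      if (is.null(g$cell_line)) "any" else paste(g$cell_line, collapse = "+"),
      "/", paste(g$state, collapse = "+")
    )
  }
  cat(sprintf("<contrast> %s: %s vs %s\n", x$name, fmt(x$group_b), fmt(x$group_a)))
  invisible(x)
}

# resolve a selector to sample names
select_samples <- function(samples, selector) {
  keep <- samples$state %in% selector$state
  if (!is.null(selector$cell_line)) {
    keep <- keep & samples$cell_line %in% selector$cell_line
  }
  samples$sample[keep]
}

resolve_contrast <- function(table, contr) {
  a <- select_samples(table$samples, contr$group_a)
  b <- select_samples(table$samples, contr$group_b)
  if (length(intersect(a, b))) abort("contrast groups overlap")
  if (length(a) < 2 || length(b) < 2) {
    abort(sprintf(
      "contrast '%s' needs >=2 samples per group (got %d and %d)",
      contr$name, length(a), length(b)
    ))
  }
  list(a = a, b = b)
}
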
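#' Gene-set collections
#'
#' A `gene_sets` object is a named list of character vectors (set members),
#' optionally carrying a per-set direction label (`"up"`, `"down"`,
#' `"undirected"`), as used for mesenchymal, invasive/proliferative,
#' kinase-substrate and transcription-factor target collections. Identifier
#' matching throughout the package is case-sensitive exact string matching;
#' any normalization (upper-casing, alias tables) is an explicit separate
#' step via [normalize_identifiers()].
#'
#' @param sets named list of character vectors; empty sets are an error.
#' @param direction optional character vector (recycled or named by set).
#' @return An object of class `gene_sets`.
#' @export
#' @examples
#' gs <- gene_sets(list(up_prog = c("P1", "P2"), down_prog = c("P3")),
#'   direction = c("up", "down")
#' )
#' lengths(gs)
gene_sets <- function(sets, direction = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) abort("sets must be named")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup)) abort(paste0("duplicate set name: ", paste(dup, collapse = ", ")))
  if (any(lengths(sets) == 0)) {
    abort(paste0(
      "empty set: ",
      paste(names(sets)[lengths(sets) == 0], collapse = ", ")
    ))
  }
  n_dup <- vapply(sets, function(m) sum(duplicated(m)), integer(1))
  if (any(n_dup > 0)) {
    warn(sprintf(
      "%d duplicated members removed across %d set(s)",
      sum(n_dup), sum(n_dup > 0)
    ))
    sets <- lapply(sets, unique)
  }
  if (is.null(direction)) {
    direction <- rep("undirected", length(sets))
  } else if (length(direction) == 1) {
    direction <- rep(direction, length(sets))
  }
  direction <- match.arg(direction, c("up", "down", "undirected"), several.ok = TRUE)
  if (length(direction) != length(sets)) abort("one direction per set required")
  structure(
    lapply(sets, as.character),
    direction = setNames(direction, names(sets)),
    n_duplicates = n_dup,
    class = "gene_sets"
  )
}

#' @export
`[.gene_sets` <- function(x, i) {
  sets <- unclass(x)[i]
  out <- gene_sets(sets, direction = unname(attr(x, "direction")[names(sets)]))
  attr(out, "n_duplicates") <- attr(x, "n_duplicates")[names(sets)]
  out
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets, sizes %s\n", length(x),
    paste(range(lengths(x)), collapse = "-")
  ))
  invisible(x)
}

#' @export
tidy.gene_sets <- function(x, ...) {
  tibble(
    set = rep(names(x), lengths(x)),
    member = unlist(x, use.names = FALSE),
    direction = rep(attr(x, "direction"), lengths(x))
  )
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Duplicate members within a set are
#' de-duplicated with a recorded warning count (`attr(x, "n_duplicates")`).
#'
#' @param path file path.
#' @return `read_gmt()`: a [gene_sets]. `write_gmt()`: the input, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 1)
  members <- lapply(parts, function(p) p[-(1:2)][nzchar(p[-(1:2)])])
  empty <- which(lengths(members) == 0)
  if (length(empty)) {
    abort(paste0("GMT line with empty set: ", paste(nm[empty], collapse = ", ")))
  }
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  gs <- gene_sets(setNames(members, nm))
  attr(gs, "description") <- setNames(desc, nm)
  gs
}

#' @rdname read_gmt
#' @param sets a [gene_sets] collection to write.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  desc <- attr(sets, "description") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Explicit identifier normalization
#'
#' Applies an optional alias map and/or upper-casing to set members or ranked
#' identifiers. Kept separate from I/O so that symbol munging is always a
#' visible, opt-in step.
#'
#' @param ids character vector of identifiers.
#' @param alias optional named character vector `c(old = "new")`.
#' @param uppercase upper-case all identifiers first.
#' @return character vector of the same length.
#' @export
normalize_identifiers <- function(ids, alias = NULL, uppercase = FALSE) {
  out <- if (uppercase) toupper(ids) else ids
  if (!is.null(alias)) {
    hit <- out %in% names(alias)
    out[hit] <- unname(alias[out[hit]])
  }
  out
}
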
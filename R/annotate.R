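scop_levels <- c(class = 1L, fold = 2L, superfamily = 3L, family = 4L)

sccs_ok <- function(code) {
  grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+){0,3}$", code)
}

sccs_prefix <- function(code, depth) {
  vapply(strsplit(code, ".", fixed = TRUE), function(p) {
    paste(p[seq_len(min(depth, length(p)))], collapse = ".")
  }, character(1))
}

new_classification <- function(ids, codes) {
  structure(tibble::tibble(id = as.character(ids), sccs = as.character(codes)),
            class = c("fs_classification", class(tibble::tibble())))
}

#' Build a hierarchical classification table in code
#'
#' @param ids Entity identifiers.
#' @param codes Dotted hierarchy codes (`class.fold.superfamily.family`, 1-4
#'   components, SCOP sccs style).
#' @return An `fs_classification` tibble with columns `id`, `sccs`.
#' @export
classification_table <- function(ids, codes) {
  ids <- as.character(ids); codes <- as.character(codes)
  if (length(ids) != length(codes)) stopf("ids and codes differ in length")
  if (anyDuplicated(ids)) stopf("duplicate entity ids in classification")
  bad <- which(!sccs_ok(codes))
  if (length(bad)) stopf("malformed classification code '%s'", codes[bad[1]])
  new_classification(ids, codes)
}

#' Read a SCOP-style classification file
#'
#' Two dialects: `dir_cla` parses whitespace-separated records in the layout
#' of SCOP `dir.cla` files (field 1 = domain id, field 4 = sccs code, `#`
#' comments skipped); `two_column` reads `id<TAB>code`. In the `dir_cla`
#' dialect an id occurring more than once denotes a multi-domain entity and
#' all its records are dropped (with a message); in `two_column`, duplicate
#' identical rows are collapsed and conflicting codes are an error.
#'
#' @param path File path.
#' @param dialect `"dir_cla"` or `"two_column"`.
#' @return An `fs_classification` tibble.
#' @export
parse_classification <- function(path, dialect = c("dir_cla", "two_column")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  recs <- lines[keep]
  lineno <- which(keep)
  if (!length(recs)) stopf("no classification records in %s", path)

  if (dialect == "dir_cla") {
    fields <- strsplit(trimws(recs), "\\s+")
    short <- which(lengths(fields) < 4)
    if (length(short)) stopf("line %d: fewer than 4 fields", lineno[short[1]])
    ids <- vapply(fields, `[[`, character(1), 1)
    codes <- vapply(fields, `[[`, character(1), 4)
  } else {
    fields <- strsplit(recs, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 2)
    if (length(short)) stopf("line %d: expected id<TAB>code", lineno[short[1]])
    ids <- vapply(fields, function(f) trimws(f[[1]]), character(1))
    codes <- vapply(fields, function(f) trimws(f[[2]]), character(1))
  }

  bad <- which(!sccs_ok(codes))
  if (length(bad)) {
    stopf("line %d: malformed classification code '%s'", lineno[bad[1]], codes[bad[1]])
  }

  if (dialect == "dir_cla") {
    dup_ids <- unique(ids[duplicated(ids)])
    if (length(dup_ids)) {
      message(sprintf("dropping %d multi-domain entit%s (%d records)",
                      length(dup_ids), if (length(dup_ids) == 1) "y" else "ies",
                      sum(ids %in% dup_ids)))
      keep2 <- !(ids %in% dup_ids)
      ids <- ids[keep2]; codes <- codes[keep2]
    }
  } else {
    tab <- unique(data.frame(id = ids, code = codes))
    conf <- tab$id[duplicated(tab$id)]
    if (length(conf)) stopf("conflicting codes for id '%s'", conf[1])
    ids <- tab$id; codes <- tab$code
  }
  new_classification(ids, codes)
}

as_level_depth <- function(level) {
  if (is.character(level)) {
    level <- match.arg(level, names(scop_levels))
    scop_levels[[level]]
  } else {
    level <- as.integer(level)
    if (level < 1 || level > 4) stopf("level depth must be 1..4")
    level
  }
}

#' Partition entities into clades at a hierarchy level
#'
#' Each entity is assigned the prefix of its code at the level's depth
#' (class = 1 ... family = 4). Singleton clades are preserved.
#'
#' @param table An `fs_classification`.
#' @param level `"class"`, `"fold"`, `"superfamily"`, `"family"`, or depth 1-4.
#' @return An `fs_partition` tibble (`id`, `cluster`).
#' @export
clade_partition <- function(table, level = "superfamily") {
  stopifnot(inherits(table, "fs_classification"))
  if (nrow(table) == 0) stopf("empty classification table")
  depth <- as_level_depth(level)
  partition(table$id, sccs_prefix(table$sccs, depth))
}

#' Shared-annotation pair adjacency
#'
#' Binary gold-standard matrix: entry `(i, j)` is 1 iff entities `i` and `j`
#' carry the same clade label at the chosen level. Pairs are unordered; the
#' diagonal is excluded from all downstream counting.
#'
#' @inheritParams clade_partition
#' @return An `fs_adjacency`: list of `ids`, binary `values`, and `level`.
#' @export
shared_annotation_adjacency <- function(table, level = "superfamily") {
  stopifnot(inherits(table, "fs_classification"))
  if (nrow(table) < 2) stopf("need at least 2 annotated entities")
  depth <- as_level_depth(level)
  lab <- sccs_prefix(table$sccs, depth)
  adj <- outer(lab, lab, `==`) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- list(table$id, table$id)
  structure(list(ids = table$id, values = adj, level = depth),
            class = "fs_adjacency")
}

#' @export
print.fs_adjacency <- function(x, ...) {
  up <- x$values[upper.tri(x$values)]
  cat(sprintf("<fs_adjacency> %d entities at depth %d: %d positive / %d total pairs\n",
              length(x$ids), x$level, sum(up), length(up)))
  invisible(x)
}
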
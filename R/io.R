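fmt_num <- function(x) sprintf("%.12g", x)

#' Write a distance matrix to disk
#'
#' Three plain-text formats: `tsv_dense` (header row of ids, one row per
#' entity with a leading id column), `phylip_square` (entity count line, then
#' `id d1 d2 ...` rows; full ids are emitted), and `tsv_triplet`
#' (`id1<TAB>id2<TAB>distance`, one unordered observed pair per line;
#' unobserved pairs are omitted). Values carry 12 significant digits so
#' write/read round-trips are exact at that precision. Dense formats require
#' a complete matrix.
#'
#' @param dist An `fs_dist`.
#' @param path Output file.
#' @param format `"tsv_dense"`, `"phylip_square"`, or `"tsv_triplet"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path,
                                  format = c("tsv_dense", "phylip_square", "tsv_triplet")) {
  stopifnot(inherits(dist, "fs_dist"))
  format <- match.arg(format)
  if (format != "tsv_triplet" && !is_complete(dist)) {
    stopf("%s is a dense format; matrix has unobserved pairs (use tsv_triplet)", format)
  }
  v <- dist$values
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv_dense") {
    writeLines(paste(c("id", dist$ids), collapse = "\t"), con)
    for (i in seq_along(dist$ids)) {
      writeLines(paste(c(dist$ids[i], fmt_num(v[i, ])), collapse = "\t"), con)
    }
  } else if (format == "phylip_square") {
    writeLines(sprintf("%5d", length(dist$ids)), con)
    for (i in seq_along(dist$ids)) {
      writeLines(paste(c(dist$ids[i], fmt_num(v[i, ])), collapse = " "), con)
    }
  } else {
    td <- tidy.fs_dist(dist)
    writeLines(paste(td$id1, td$id2, fmt_num(td$distance), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a distance matrix
#'
#' Counterpart of [write_distance_matrix()]. Triplet ids are ordered by first
#' appearance and entries mirrored symmetrically; unlisted pairs are
#' unobserved. Dense inputs are validated for symmetry (relative tolerance
#' `1e-9`); conflicting duplicate triplet entries, negative distances, and
#' ragged rows are rejected with the offending location.
#'
#' @param path Input file.
#' @param format `"tsv_dense"`, `"phylip_square"`, or `"tsv_triplet"`.
#' @return An `fs_dist`.
#' @export
read_distance_matrix <- function(path,
                                 format = c("tsv_dense", "phylip_square", "tsv_triplet")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("%s: empty file", path)

  if (format == "tsv_triplet") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad)) stopf("%s line %d: expected id1<TAB>id2<TAB>distance", path, bad[1])
    id1 <- vapply(parts, `[[`, character(1), 1)
    id2 <- vapply(parts, `[[`, character(1), 2)
    val <- as.numeric(vapply(parts, `[[`, character(1), 3))
    if (anyNA(val)) stopf("%s line %d: non-numeric distance", path, which(is.na(val))[1])
    if (any(val < 0)) stopf("%s line %d: negative distance", path, which(val < 0)[1])
    ids <- unique(c(rbind(id1, id2)))
    n <- length(ids)
    v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(v) <- 0
    for (k in seq_along(val)) {
      i <- id1[k]; j <- id2[k]
      old <- v[i, j]
      if (!is.na(old) && old != val[k]) {
        stopf("%s line %d: conflicting duplicate for pair (%s, %s)", path, k, i, j)
      }
      v[i, j] <- v[j, i] <- val[k]
    }
    return(distance_matrix(v, ids = ids))
  }

  if (format == "tsv_dense") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- parts[[1]][-1]
    rows <- parts[-1]
  } else {
    n_declared <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n_declared)) stopf("%s: first line must be the entity count", path)
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    if (length(rows) != n_declared) {
      stopf("%s: declared %d rows, found %d", path, n_declared, length(rows))
    }
    ids <- vapply(rows, `[[`, character(1), 1)
  }
  n <- length(ids)
  bad <- which(lengths(rows) != n + 1)
  if (length(bad)) stopf("%s row %d: ragged row (expected %d values)", path, bad[1], n)
  if (format == "tsv_dense") {
    rid <- vapply(rows, `[[`, character(1), 1)
    if (!identical(rid, ids)) stopf("%s: row ids do not match header ids", path)
  }
  v <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  if (anyNA(v)) stopf("%s: non-numeric distance entries", path)
  if (any(v < 0)) stopf("%s: negative distance entries", path)
  dimnames(v) <- list(ids, ids)
  distance_matrix(v, ids = ids)   # symmetry validated by the constructor
}

#' Write map coordinates as TSV
#'
#' Header `id<TAB>dim1...dimr`, one row per entity. A sidecar
#' `<path>.meta.tsv` records method, stress, iterations and seed so a map's
#' provenance travels with its coordinates.
#'
#' @param config An `fs_config`.
#' @param path Output file.
#' @param sidecar Write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(config, path, sidecar = TRUE) {
  stopifnot(inherits(config, "fs_config"))
  con <- file(path, "w")
  writeLines(paste(c("id", colnames(config$coords)), collapse = "\t"), con)
  for (i in seq_along(config$ids)) {
    writeLines(paste(c(config$ids[i], fmt_num(config$coords[i, ])), collapse = "\t"), con)
  }
  close(con)
  if (sidecar) {
    meta <- c(
      paste0("method\t", config$method),
      paste0("dim\t", config$dim),
      paste0("stress\t", fmt_num(config$stress)),
      paste0("iterations\t", config$iterations),
      if (!is.null(config$seed)) paste0("seed\t", config$seed)
    )
    writeLines(meta, paste0(path, ".meta.tsv"))
  }
  invisible(path)
}

#' Read map coordinates written by [write_coordinates()]
#'
#' @param path Coordinates TSV.
#' @return An `fs_config` (metadata restored from the sidecar when present).
#' @export
read_coordinates <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- tab[[1]]
  coords <- apply(as.matrix(tab[, -1, drop = FALSE]), 2, as.numeric)
  coords <- matrix(coords, nrow = length(ids))
  cfg <- new_config(ids, coords, "cmds")
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), "\t", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, `[[`, character(1), 2),
                            vapply(kv, `[[`, character(1), 1))
    cfg$method <- meta[["method"]] %||% cfg$method
    cfg$stress <- as.numeric(meta["stress"])
    cfg$iterations <- as.integer(meta["iterations"] %||% 0)
    if (!is.na(meta["seed"])) cfg$seed <- as.integer(meta[["seed"]])
  }
  cfg
}

#' Write a partition or classification as 2-column TSV
#'
#' @param x An `fs_partition` (`id<TAB>cluster`) or `fs_classification`
#'   (`id<TAB>sccs`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(x, path) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  writeLines(paste(x[[1]], x[[2]], sep = "\t"), path)
  invisible(path)
}

needs_quoting <- function(label) grepl("[][ \t():;,']", label)

quote_label <- function(label) {
  ifelse(needs_quoting(label),
         paste0("'", gsub("'", "''", label), "'"),
         label)
}

newick_node <- function(node) {
  if (is_leaf(node)) return(quote_label(node$leaf))
  inner <- mapply(function(ch, len) paste0(newick_node(ch), ":", fmt_num(len)),
                  node$children, node$lengths)
  paste0("(", paste(inner, collapse = ","), ")")
}

newick_string <- function(tree, clamp_negative = FALSE) {
  root <- tree$root
  if (clamp_negative) root <- clamp_lengths(root)
  paste0(newick_node(root), ";")
}

clamp_lengths <- function(node) {
  if (is_leaf(node)) return(node)
  node$lengths <- pmax(node$lengths, 0)
  node$children <- lapply(node$children, clamp_lengths)
  node
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths included; a trifurcating root is allowed; labels containing
#' spaces or Newick metacharacters are quoted. Negative neighbor-joining
#' branch lengths are kept by default (`clamp_negative = TRUE` zeroes them
#' for viewers that reject negatives).
#'
#' @param tree An `fs_dendro`.
#' @param path Output file.
#' @param clamp_negative Clamp negative branch lengths to zero on output.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, clamp_negative = FALSE) {
  stopifnot(inherits(tree, "fs_dendro"))
  writeLines(newick_string(tree, clamp_negative = clamp_negative), path)
  invisible(path)
}

aligners <- c("CE", "Dali", "FATCAT", "MATT")

#' Parse a structure-space representation code
#'
#' The naming code identifies a representation by aligner, score type,
#' projection and dimensionality: `"Dali"` (raw pairwise scores), `"CE(Z)"`
#' (probability pairwise), `"MATT(ZC24)"` (probability scores, classical
#' scaling, 24 dimensions), `"Dali(S12)"` (raw scores, SMACOF, 12
#' dimensions). `Z` marks probability scores, `C` classical scaling, `S`
#' SMACOF; the dimension may be omitted for a map family (`"Dali(C)"`).
#'
#' @param code Representation code string.
#' @return A list of class `fs_repcode`: `aligner`, `score_type`
#'   (`raw`/`probability`), `projection` (`pairwise`/`cmds`/`smacof`), `dim`
#'   (integer or `NA`).
#' @export
parse_representation_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1, nzchar(code))
  m <- regexec("^([A-Za-z][A-Za-z0-9_-]*)(\\(([Z]?)([CS]?)([0-9]*)\\))?$", code)
  g <- regmatches(code, m)[[1]]
  if (!length(g)) stopf("cannot parse representation code '%s'", code)
  aligner <- g[2]
  has_paren <- nzchar(g[3])
  z <- nzchar(g[4])
  proj_flag <- g[5]
  dim_str <- g[6]
  if (has_paren && !z && !nzchar(proj_flag) && !nzchar(dim_str)) {
    stopf("empty parenthetical in representation code '%s'", code)
  }
  projection <- if (!nzchar(proj_flag)) "pairwise" else if (proj_flag == "C") "cmds" else "smacof"
  if (projection == "pairwise" && nzchar(dim_str)) {
    stopf("representation code '%s': dimension given without a projection flag (position %d)",
          code, regexpr("[0-9]", code))
  }
  structure(
    list(aligner = aligner,
         score_type = if (z) "probability" else "raw",
         projection = projection,
         dim = if (nzchar(dim_str)) as.integer(dim_str) else NA_integer_),
    class = "fs_repcode"
  )
}

#' Render a representation code back to its string form
#'
#' Exact inverse of [parse_representation_code()].
#'
#' @param rep An `fs_repcode`.
#' @return The code string.
#' @export
format_representation_code <- function(rep) {
  stopifnot(inherits(rep, "fs_repcode"))
  z <- if (rep$score_type == "probability") "Z" else ""
  proj <- switch(rep$projection, pairwise = "", cmds = "C", smacof = "S")
  dim <- if (!is.na(rep$dim)) as.character(rep$dim) else ""
  inner <- paste0(z, proj, dim)
  if (nzchar(inner)) paste0(rep$aligner, "(", inner, ")") else rep$aligner
}

#' @export
print.fs_repcode <- function(x, ...) {
  cat(sprintf("<fs_repcode> %s: %s %s scores, %s%s\n",
              format_representation_code(x), x$aligner, x$score_type,
              x$projection,
              if (!is.na(x$dim)) sprintf(" in %dD", x$dim) else ""))
  invisible(x)
}

#' Read a pairwise similarity score file
#'
#' Same formats as [read_distance_matrix()], but the result is a
#' [similarity_matrix()]; asymmetric dense input is accepted (symmetrize
#' downstream with [symmetrize()]).
#'
#' @param path Input file.
#' @param format `"tsv_dense"`, `"phylip_square"`, or `"tsv_triplet"`.
#' @inheritParams similarity_matrix
#' @return An `fs_similarity`.
#' @export
read_similarity_matrix <- function(path,
                                   format = c("tsv_dense", "phylip_square", "tsv_triplet"),
                                   polarity = "similarity",
                                   aligner = "unknown", score_type = "raw") {
  format <- match.arg(format)
  if (format == "tsv_triplet") {
    d <- read_distance_matrix(path, format)   # triplet reader is polarity-neutral
    return(similarity_matrix(d$values, ids = d$ids, observed = d$observed,
                             polarity = polarity, aligner = aligner,
                             score_type = score_type))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "tsv_dense") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- parts[[1]][-1]
    rows <- parts[-1]
  } else {
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    ids <- vapply(rows, `[[`, character(1), 1)
  }
  n <- length(ids)
  v <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(v) <- list(ids, ids)
  similarity_matrix(v, ids = ids, polarity = polarity, aligner = aligner,
                    score_type = score_type)
}
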
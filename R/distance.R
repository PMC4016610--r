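#' Symmetric distance matrix with observation mask
#'
#' Non-negative symmetric dissimilarities `delta_ij` with a zero diagonal.
#' Entries for pairs never scored by the aligner are marked unobserved and
#' carried as `NA`; the weighted SMACOF path uses the mask directly, while
#' classical MDS requires imputation first ([impute_missing()]).
#'
#' @param values Square numeric matrix of dissimilarities.
#' @param ids Character identifiers (defaults to row names or `v1..vN`).
#' @param observed Logical mask; defaults to non-`NA` entries. The diagonal is
#'   always observed.
#' @param cap Optional cap `s_n` recorded by [similarity_to_distance()].
#' @param tol Relative symmetry tolerance for validation.
#' @return An object of class `fs_dist`.
#' @export
distance_matrix <- function(values, ids = NULL, observed = NULL, cap = NULL,
                            tol = 1e-9) {
  assert_square(values, "distance values")
  n <- nrow(values)
  if (is.null(ids)) ids <- rownames(values) %||% paste0("v", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stopf("length(ids) != nrow(values)")
  if (anyDuplicated(ids)) stopf("entity ids must be unique")
  if (is.null(observed)) observed <- !is.na(values)
  observed <- observed & t(observed)
  diag(observed) <- TRUE
  values[!observed] <- NA_real_
  diag(values) <- 0
  scale <- max(abs(values), 1, na.rm = TRUE)
  asym <- abs(values - t(values))
  if (any(asym > tol * scale, na.rm = TRUE)) {
    stopf("distance matrix is not symmetric (max deviation %.3g)",
          max(asym, na.rm = TRUE))
  }
  values <- (values + t(values)) / 2   # remove round-off asymmetry
  if (any(values < 0, na.rm = TRUE)) stopf("negative distances are not allowed")
  dimnames(values) <- dimnames(observed) <- list(ids, ids)
  structure(list(ids = ids, values = values, observed = observed, cap = cap),
            class = "fs_dist")
}

#' @export
print.fs_dist <- function(x, ...) {
  n <- length(x$ids)
  off <- x$observed; diag(off) <- FALSE
  frac <- if (n > 1) sum(off[upper.tri(off)]) / (n * (n - 1) / 2) else 1
  cat(sprintf("<fs_dist> %d entities, %.1f%% of pairs observed%s\n",
              n, 100 * frac,
              if (!is.null(x$cap)) sprintf(", cap s_n = %.6g", x$cap) else ""))
  invisible(x)
}

#' @export
as.matrix.fs_dist <- function(x, ...) x$values

#' @export
as.dist.fs_dist <- function(m, ...) stats::as.dist(m$values)

is_complete <- function(dist) all(dist$observed)

#' Long-format view of a distance matrix
#'
#' @param x An `fs_dist` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered observed pair
#'   (`id1`, `id2`, `distance`).
#' @export
#' @exportS3Method generics::tidy
tidy.fs_dist <- function(x, ...) {
  n <- length(x$ids)
  ut <- upper.tri(x$values)
  keep <- ut & x$observed
  idx <- which(keep, arr.ind = TRUE)
  tibble::tibble(id1 = x$ids[idx[, 1]], id2 = x$ids[idx[, 2]],
                 distance = x$values[keep])
}

#' Subset a distance matrix by entity id
#'
#' @param dist An `fs_dist` object.
#' @param ids Ids to keep, in the order given.
#' @return The restricted `fs_dist`.
#' @export
dist_subset <- function(dist, ids) {
  stopifnot(inherits(dist, "fs_dist"))
  missing <- setdiff(ids, dist$ids)
  if (length(missing)) stopf("ids not in distance matrix: %s",
                             paste(utils::head(missing, 5), collapse = ", "))
  distance_matrix(dist$values[ids, ids, drop = FALSE], ids = ids,
                  observed = dist$observed[ids, ids, drop = FALSE],
                  cap = dist$cap)
}

#' Fill unobserved distances
#'
#' Classical MDS needs a complete matrix. Unobserved off-diagonal entries are
#' filled with the recorded cap `s_n` (`mode = "cap"`, default — an unaligned
#' pair is assumed maximally distant) or with the mean observed distance.
#'
#' @param dist An `fs_dist` object.
#' @param mode `"cap"` or `"mean"`.
#' @return A fully observed `fs_dist`; a `"fs_imputed"` attribute records the
#'   number of filled pairs.
#' @export
impute_missing <- function(dist, mode = c("cap", "mean")) {
  stopifnot(inherits(dist, "fs_dist"))
  mode <- match.arg(mode)
  v <- dist$values
  miss <- !dist$observed
  if (!any(miss)) return(dist)
  fill <- switch(mode,
    cap = {
      if (is.null(dist$cap)) stopf("mode 'cap' needs a recorded cap; none present")
      dist$cap
    },
    mean = {
      off <- dist$observed; diag(off) <- FALSE
      mean(v[off & upper.tri(off)])
    })
  v[miss] <- fill
  out <- distance_matrix(v, ids = dist$ids, cap = dist$cap)
  attr(out, "fs_imputed") <- sum(miss[upper.tri(miss)])
  out
}
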
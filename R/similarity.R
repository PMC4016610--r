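#' Pairwise structure-alignment score matrix
#'
#' Container for raw or probability alignment scores between `N` entities
#' (protein structures, typically). Scores may be incomplete: aligners such as
#' Dali only attempt a small fraction of all pairs, so every entry carries an
#' observation flag. The diagonal is ignored by all downstream operations.
#'
#' @param values Square numeric matrix of scores `s_ij`.
#' @param ids Character vector of entity identifiers; defaults to the row
#'   names of `values` or `v1..vN`.
#' @param observed Logical matrix marking which pairs carry a real score.
#'   Defaults to non-`NA` entries of `values`.
#' @param polarity `"similarity"` (larger = more alike, the usual case) or
#'   `"dissimilarity"` (e.g. the MATT probability score, already a distance).
#' @param aligner Free-text tag naming the alignment program.
#' @param score_type `"raw"` or `"probability"`.
#'
#' @return An object of class `fs_similarity`.
#' @seealso [similarity_to_distance()], [symmetrize()]
#' @export
similarity_matrix <- function(values, ids = NULL,
                              observed = NULL,
                              polarity = c("similarity", "dissimilarity"),
                              aligner = "unknown",
                              score_type = c("raw", "probability")) {
  assert_square(values, "similarity values")
  polarity <- match.arg(polarity)
  score_type <- match.arg(score_type)
  n <- nrow(values)
  if (is.null(ids)) ids <- rownames(values) %||% paste0("v", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stopf("length(ids) != nrow(values)")
  if (anyDuplicated(ids)) stopf("entity ids must be unique")
  if (is.null(observed)) observed <- !is.na(values)
  assert_square(observed, "observed mask")
  observed <- observed | t(observed)      # a pair seen in either direction counts
  diag(observed) <- TRUE
  values[!observed] <- NA_real_
  dimnames(values) <- dimnames(observed) <- list(ids, ids)
  structure(
    list(ids = ids, values = values, observed = observed,
         polarity = polarity, aligner = aligner, score_type = score_type),
    class = "fs_similarity"
  )
}

#' @export
print.fs_similarity <- function(x, ...) {
  n <- length(x$ids)
  off <- x$observed; diag(off) <- FALSE
  cat(sprintf("<fs_similarity> %d entities, %s %s scores (%s), %.1f%% of pairs observed\n",
              n, x$aligner, x$score_type, x$polarity,
              100 * sum(off[upper.tri(off)]) / max(1, n * (n - 1) / 2)))
  invisible(x)
}

#' @export
as.matrix.fs_similarity <- function(x, ...) x$values

is_symmetric_scores <- function(sim, tol = 1e-9) {
  v <- sim$values
  both <- sim$observed & t(sim$observed)
  v[!both] <- 0
  vt <- t(v); vt[!both] <- 0
  scale <- max(abs(v), 1)
  max(abs(v - vt)) <= tol * scale
}

#' Symmetrize an alignment score matrix
#'
#' Aligners may report `s_ij != s_ji` or score only one direction of a pair.
#' Pairs observed in both directions are combined by `rule`; pairs observed in
#' one direction are copied to the other.
#'
#' @param sim An [similarity_matrix()] object.
#' @param rule Combination rule for doubly-observed pairs: `"mean"` (default),
#'   `"min"` or `"max"`.
#' @return A symmetric `fs_similarity`.
#' @export
symmetrize <- function(sim, rule = c("mean", "min", "max")) {
  stopifnot(inherits(sim, "fs_similarity"))
  rule <- match.arg(rule)
  v <- sim$values
  vt <- t(v)
  obs <- sim$observed & !is.na(v)
  obst <- t(obs)
  out <- v
  both <- obs & obst
  f <- switch(rule, mean = function(a, b) (a + b) / 2, min = pmin, max = pmax)
  out[both] <- f(v[both], vt[both])
  onlyt <- obst & !obs
  out[onlyt] <- vt[onlyt]
  similarity_matrix(out, ids = sim$ids, observed = obs | obst,
                    polarity = sim$polarity, aligner = sim$aligner,
                    score_type = sim$score_type)
}

#' Nearest-rank index of the p-th percentile over all pairs
#'
#' For `N` entities there are `M = N(N-1)/2` unordered pairs; the index of the
#' p-th percentile in the ascending-sorted score list is
#' `n = round(p/100 * (M + 1))` (half-up), clamped to `[1, M]`.
#'
#' @param p Percentile in `[0, 100]`.
#' @param n_entities Number of entities `N` (>= 2).
#' @return Integer index into the sorted pair-score list.
#' @export
percentile_index <- function(p, n_entities) {
  if (!is.numeric(p) || p < 0 || p > 100) stopf("p must be in [0, 100]")
  if (!is.numeric(n_entities) || n_entities < 2) stopf("need at least 2 entities")
  m <- n_entities * (n_entities - 1) / 2
  pair_rank_index(p, m)
}

# nearest-rank index for an explicit pair count (sparse inputs rank only
# observed pairs)
pair_rank_index <- function(p, n_pairs) {
  n <- round_half_up(p / 100 * (n_pairs + 1))
  as.integer(min(max(n, 1), n_pairs))
}

observed_upper_scores <- function(sim) {
  off <- sim$observed
  diag(off) <- FALSE
  keep <- off & upper.tri(off)
  sim$values[keep]
}

#' Select the distance cap s_n at a percentile rank
#'
#' Returns the score whose ascending rank among all observed off-diagonal
#' pair scores is the nearest-rank index of the `p`-th percentile. Used as the
#' maximum score `s_n` in [similarity_to_distance()] so that a handful of
#' outlier pairs does not dominate the distance scale.
#'
#' @inheritParams symmetrize
#' @param p Percentile in `[0, 100]`; the mapping pipeline default is 99.95.
#' @return The selected score `s_n` (scalar).
#' @export
select_max_score <- function(sim, p = 99.95) {
  stopifnot(inherits(sim, "fs_similarity"))
  s <- observed_upper_scores(sim)
  s <- s[!is.na(s)]
  if (length(s) == 0) stopf("no observed off-diagonal scores")
  sort(s)[pair_rank_index(p, length(s))]
}

#' Convert similarity scores to capped distances
#'
#' Subtracts similarity scores from the percentile cap `s_n`
#' (see [select_max_score()]): `delta_ij = s_n - s_ij` for `s_ij < s_n`, zero
#' on the diagonal. Pairs at least as similar as the cap get distance 0 under
#' `overflow_mode = "clamp"` (default: highest similarity means zero distance)
#' or `s_n` under `"literal"`. Unobserved pairs stay unobserved.
#'
#' @inheritParams select_max_score
#' @param overflow_mode How to treat scores `>= s_n`: `"clamp"` or `"literal"`.
#' @return A [distance_matrix()] with the cap recorded.
#' @export
similarity_to_distance <- function(sim, p = 99.95,
                                   overflow_mode = c("clamp", "literal")) {
  stopifnot(inherits(sim, "fs_similarity"))
  overflow_mode <- match.arg(overflow_mode)
  if (sim$polarity == "dissimilarity") {
    stopf("input already holds dissimilarities; use passthrough_dissimilarity()")
  }
  if (!is_symmetric_scores(sim)) {
    stopf("scores are not symmetric; call symmetrize() first")
  }
  sn <- select_max_score(sim, p)
  v <- sim$values
  d <- sn - v
  over <- !is.na(v) & v >= sn
  d[over] <- if (overflow_mode == "clamp") 0 else sn
  d[!sim$observed] <- NA_real_
  diag(d) <- 0
  distance_matrix(d, ids = sim$ids, observed = sim$observed, cap = sn)
}

#' Pass a dissimilarity-polarity score matrix through as distances
#'
#' Some probability transforms (MATT's, notably) already yield a
#' dissimilarity, so no cap subtraction applies: values are copied, the
#' diagonal is forced to zero, and negative entries are rejected.
#'
#' @inheritParams symmetrize
#' @return A [distance_matrix()] (no cap recorded).
#' @export
passthrough_dissimilarity <- function(sim) {
  stopifnot(inherits(sim, "fs_similarity"))
  if (sim$polarity != "dissimilarity") {
    stopf("input has similarity polarity; use similarity_to_distance()")
  }
  v <- sim$values
  diag(v) <- 0
  if (any(v < 0, na.rm = TRUE)) stopf("negative dissimilarity values are not valid distances")
  distance_matrix(v, ids = sim$ids, observed = sim$observed)
}
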
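# pair universe shared by all ROC operations: unordered pairs of annotated
# entities. Unobserved distances are dropped from the universe by default, or
# kept at +Inf (never within a finite neighborhood) under "infinite" — the
# honest baseline for sparse alignment sets, where most pairs simply cannot
# be called.
roc_pairs <- function(dist, adj, unobserved = c("exclude", "infinite")) {
  stopifnot(inherits(dist, "fs_dist"), inherits(adj, "fs_adjacency"))
  unobserved <- match.arg(unobserved)
  ids <- intersect(dist$ids, adj$ids)
  if (length(ids) < 2) stopf("fewer than 2 entities shared between distances and annotation")
  d <- dist$values[ids, ids, drop = FALSE]
  obs <- dist$observed[ids, ids, drop = FALSE]
  a <- adj$values[ids, ids, drop = FALSE]
  if (unobserved == "infinite") d[!obs] <- Inf
  keep <- if (unobserved == "exclude") upper.tri(d) & obs else upper.tri(d)
  list(ids = ids, distance = d[keep], positive = a[keep] == 1L)
}

#' Confusion counts at a distance threshold
#'
#' A pair is predicted positive iff its distance is `<= t` (ties inclusive);
#' true positives are pairs sharing the annotation. Counts run over unordered
#' pairs of annotated entities with an observed distance.
#'
#' @param dist An `fs_dist`.
#' @param adj An [shared_annotation_adjacency()] gold standard.
#' @param t Distance threshold.
#' @param unobserved Sparse-matrix pair universe: `"exclude"` unobserved pairs
#'   (default) or keep them at `"infinite"` distance (predicted negative at
#'   every finite threshold).
#' @return Tibble with one row: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(dist, adj, t, unobserved = "exclude") {
  pr <- roc_pairs(dist, adj, unobserved)
  pred <- pr$distance <= t
  tibble::tibble(
    tp = sum(pred & pr$positive), fp = sum(pred & !pr$positive),
    tn = sum(!pred & !pr$positive), fn = sum(!pred & pr$positive)
  )
}

#' Exhaustive ROC analysis of a structure-space representation
#'
#' Sweeps the classification threshold over every unique observed distance
#' (plus a sentinel below the minimum so the curve starts at (0, 0)),
#' computing FPR, TPR, TNR and the total true classification rate
#' TCR = TPR + TNR at each. The AUC is the trapezoidal integral of TPR over
#' FPR; the best threshold is the smallest one maximizing TCR.
#'
#' @inheritParams confusion_at_threshold
#' @return An `fs_roc` object: `curve` tibble
#'   (`threshold`, `fpr`, `tpr`, `tnr`, `tcr`), `auc`, `best_threshold`,
#'   `best_tcr`, and the positive/negative pair counts.
#' @export
roc_curve <- function(dist, adj, unobserved = "exclude") {
  pr <- roc_pairs(dist, adj, unobserved)
  pos <- sum(pr$positive)
  neg <- sum(!pr$positive)
  if (pos == 0 || neg == 0) {
    stopf("degenerate classes: need at least one positive and one negative pair")
  }
  ord <- order(pr$distance)
  d <- pr$distance[ord]
  y <- pr$positive[ord]
  uniq <- !duplicated(d, fromLast = TRUE)   # last index of each unique distance
  thr <- d[uniq]
  tp <- cumsum(y)[uniq]
  fp <- cumsum(!y)[uniq]
  sentinel <- thr[1] - max(1, abs(thr[1]))  # guarantees the (0,0) point
  thr <- c(sentinel, thr)
  tp <- c(0, tp); fp <- c(0, fp)
  tpr <- tp / pos
  fpr <- fp / neg
  tnr <- (neg - fp) / neg
  tcr <- tpr + tnr
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # ties resolved to the smallest threshold; the sub-minimum sentinel only
  # anchors the curve at (0,0) and is never selected as an operating point
  best <- which.max(tcr[-1]) + 1L
  structure(
    list(curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr,
                                tnr = tnr, tcr = tcr),
         auc = auc, best_threshold = thr[best], best_tcr = tcr[best],
         n_positive = pos, n_negative = neg),
    class = "fs_roc"
  )
}

#' @export
print.fs_roc <- function(x, ...) {
  cat(sprintf("<fs_roc> %d+/%d- pairs, AUC %.4f, best threshold %.6g (TCR %.4f)\n",
              x$n_positive, x$n_negative, x$auc, x$best_threshold, x$best_tcr))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
#' @rdname roc_curve
#' @param x An `fs_roc` object.
#' @param ... Unused.
tidy.fs_roc <- function(x, ...) x$curve

#' @export
#' @exportS3Method generics::glance
#' @rdname roc_curve
glance.fs_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, best_threshold = x$best_threshold,
                 best_tcr = x$best_tcr, n_positive = x$n_positive,
                 n_negative = x$n_negative)
}

#' Per-clade precision, recall and F1 at a threshold
#'
#' Over pairs with at least one member in the clade: TP = within-clade pairs
#' at distance `<= t`, FN = within-clade pairs beyond `t`, FP = mixed pairs
#' (exactly one member in the clade) within `t`. Precision defaults to 1 when
#' nothing is predicted; F1 is 0 when TP is 0.
#'
#' @param dist An `fs_dist`.
#' @param part An `fs_partition` of clade memberships.
#' @param clade Clade label, or `NULL` for every clade with >= 2 members.
#' @param t Distance threshold (typically `best_threshold` from [roc_curve()]).
#' @return Tibble `clade`, `n`, `precision`, `recall`, `f1`.
#' @export
clade_prf <- function(dist, part, clade = NULL, t) {
  stopifnot(inherits(dist, "fs_dist"), inherits(part, "fs_partition"))
  part <- part[part$id %in% dist$ids, ]
  sets <- partition_sets(partition(part$id, part$cluster))
  clades <- clade %||% names(sets)[lengths(sets) >= 2]
  rows <- lapply(clades, function(cl) {
    members <- sets[[cl]]
    if (is.null(members)) stopf("clade '%s' not present", cl)
    if (length(members) < 2) stopf("clade '%s' is a singleton: recall undefined", cl)
    others <- setdiff(part$id, members)
    dmm <- dist$values[members, members, drop = FALSE]
    omm <- dist$observed[members, members, drop = FALSE]
    within <- dmm[upper.tri(dmm) & omm]
    mixed <- dist$values[members, others, drop = FALSE]
    mixed <- mixed[dist$observed[members, others, drop = FALSE]]
    tp <- sum(within <= t); fn <- sum(within > t); fp <- sum(mixed <= t)
    precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
    recall <- tp / (tp + fn)
    f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
    tibble::tibble(clade = cl, n = length(members),
                   precision = precision, recall = recall, f1 = f1)
  })
  dplyr::bind_rows(rows)
}
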
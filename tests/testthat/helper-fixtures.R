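# shared fixtures and independent oracles; everything is built in code

mk_dist <- function(m, ids = NULL) {
  if (is.null(ids)) ids <- letters[seq_len(nrow(m))]
  dimnames(m) <- list(ids, ids)
  distance_matrix(m, ids = ids)
}

mk_sim <- function(m, ids = NULL, ...) {
  if (is.null(ids)) ids <- letters[seq_len(nrow(m))]
  dimnames(m) <- list(ids, ids)
  similarity_matrix(m, ids = ids, ...)
}

# distance matrix from a coordinate matrix
coords_dist <- function(x, ids = NULL) {
  mk_dist(as.matrix(stats::dist(x)), ids = ids)
}

# adjacency with full control over which pairs are positive:
# `pos` is a 2-column matrix of id pairs
mk_adjacency <- function(ids, pos) {
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(pos))) {
    a[pos[k, 1], pos[k, 2]] <- a[pos[k, 2], pos[k, 1]] <- 1L
  }
  structure(list(ids = ids, values = a, level = 3L), class = "fs_adjacency")
}

# 4-entity distance matrix with chosen positive/negative pair distances:
# positives (a,b), (c,d); negatives (a,c), (b,d); pairs (a,d), (b,c) unobserved
mk_roc_case <- function(pos_d, neg_d) {
  ids <- c("a", "b", "c", "d")
  m <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 0
  m["a", "b"] <- pos_d[1]; m["c", "d"] <- pos_d[2]
  m["a", "c"] <- neg_d[1]; m["b", "d"] <- neg_d[2]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  list(dist = distance_matrix(m),
       adj = mk_adjacency(ids, rbind(c("a", "b"), c("c", "d"))))
}

# random labelled pair instance for ROC oracles: distances + labels directly
# realized as a star-free synthetic matrix is unnecessary; we build a
# (2k)-entity matrix whose observed pairs are exactly the k instances
mk_pair_instance <- function(n_pairs, seed) {
  set.seed(seed)
  d <- round(stats::runif(n_pairs, 0, 10), 2)   # rounding provokes ties
  y <- stats::runif(n_pairs) < 0.5
  if (all(y) || !any(y)) y[1] <- !y[1]
  ids <- paste0("e", seq_len(2 * n_pairs))
  m <- matrix(NA_real_, 2 * n_pairs, 2 * n_pairs, dimnames = list(ids, ids))
  diag(m) <- 0
  pos <- NULL
  for (k in seq_len(n_pairs)) {
    i <- 2 * k - 1; j <- 2 * k
    m[i, j] <- m[j, i] <- d[k]
    if (y[k]) pos <- rbind(pos, c(ids[i], ids[j]))
  }
  if (is.null(pos)) pos <- matrix(character(0), 0, 2)
  list(dist = distance_matrix(m), adj = mk_adjacency(ids, pos),
       d = d, y = y)
}

# Mann-Whitney oracle: P(d_pos < d_neg) + 1/2 P(d_pos == d_neg), brute force
bf_auc <- function(d, y) {
  pos <- d[y]; neg <- d[!y]
  total <- 0
  for (p in pos) total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exhaustive TCR maximization oracle
bf_best_threshold <- function(d, y) {
  ts <- sort(unique(d))
  tcr <- vapply(ts, function(t) {
    sum(y & d <= t) / sum(y) + sum(!y & d > t) / sum(!y)
  }, numeric(1))
  list(threshold = ts[which.max(tcr)], tcr = max(tcr))
}

# random additive tree via ape; returns the phylo and its path distances
random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  ph <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.5, 3))
  ph$tip.label <- paste0("t", seq_len(n_taxa))
  list(phylo = ph, dist = mk_dist(ape::cophenetic.phylo(ph)[ph$tip.label, ph$tip.label],
                                  ids = ph$tip.label))
}

# independent max-linkage checker: each leaf joins the highest ancestor whose
# leaf set passes the criterion; groups of leaves sharing that ancestor form
# the partition (logic independent of the recursive-descent implementation)
bf_max_linkage <- function(tree, dist, t) {
  nodes <- list()
  walk <- function(node, path) {
    k <- length(nodes) + 1
    nodes[[k]] <<- list(node = node, path = path)
    if (!foldspace:::is_leaf(node)) {
      for (ch in node$children) walk(ch, c(path, k))
    }
  }
  walk(tree$root, integer(0))
  leafsets <- lapply(nodes, function(e) foldspace:::node_leaves(e$node))
  ok <- vapply(leafsets, function(lv) {
    length(lv) == 1 || max(dist$values[lv, lv]) <= t
  }, logical(1))
  assignment <- character(0)
  for (k in seq_along(nodes)) {
    e <- nodes[[k]]
    if (foldspace:::is_leaf(e$node)) {
      anc <- c(e$path, k)           # root-to-leaf indices
      top <- anc[ok[anc]][1]        # highest satisfying ancestor
      assignment[e$node$leaf] <- as.character(top)
    }
  }
  split(names(assignment), assignment)
}

# canonical form of a partition for comparison (sets of sorted member sets)
canon_partition <- function(part) {
  sets <- if (inherits(part, "fs_partition")) {
    split(part$id, part$cluster)
  } else {
    part
  }
  unname(sort(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))))
}

# memoized default synthetic space + pipeline used by several test files
fs_cache <- new.env(parent = emptyenv())

default_space <- function() {
  if (is.null(fs_cache$space)) fs_cache$space <- generate_space(synth_params(seed = 2))
  fs_cache$space
}

default_pipeline <- function() {
  if (is.null(fs_cache$pipeline)) {
    sp <- default_space()
    cfg <- smacof(sp$distances, r = 12)
    md <- config_distances(cfg)
    adj <- shared_annotation_adjacency(sp$classification, "superfamily")
    roc <- roc_curve(md, adj)
    tree <- neighbor_joining(md)
    part <- max_linkage_clusters(tree, md, roc$best_threshold)
    truth <- clade_partition(sp$classification, "superfamily")
    fs_cache$pipeline <- list(space = sp, config = cfg, map_dist = md,
                              adj = adj, roc = roc, tree = tree,
                              clusters = part, truth = truth)
  }
  fs_cache$pipeline
}
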
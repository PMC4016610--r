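# dendrogram nodes are nested lists:
#   leaf:     list(leaf = "<id>")
#   internal: list(leaf = NULL, children = list(<node>...), lengths = c(...))
new_leaf <- function(id) list(leaf = id)
new_inner <- function(children, lengths) {
  list(leaf = NULL, children = children, lengths = lengths)
}
is_leaf <- function(node) !is.null(node$leaf)

node_leaves <- function(node) {
  if (is_leaf(node)) return(node$leaf)
  unlist(lapply(node$children, node_leaves), use.names = FALSE)
}

new_dendro <- function(root, ids) {
  structure(list(root = root, ids = ids), class = "fs_dendro")
}

#' @export
print.fs_dendro <- function(x, ...) {
  cat(sprintf("<fs_dendro> %d leaves (neighbor-joining dendrogram)\n",
              length(x$ids)))
  invisible(x)
}

#' Canonical neighbor-joining dendrogram
#'
#' Saitou-Nei neighbor joining with exhaustive search of the Q-criterion at
#' every step: join the pair minimizing
#' `Q_ij = (n-2) d_ij - r_i - r_j`, assign branch lengths by the two-point
#' formulas, collapse, repeat. The final three-way join is kept as a
#' (trifurcating) root; two taxa reduce to a single edge split at its
#' midpoint. Ties in Q are broken by the lexicographically smallest index
#' pair, making the output deterministic. Negative branch lengths are kept as
#' computed (downstream clustering uses original distances, not branch
#' lengths).
#'
#' @param dist A complete [distance_matrix()] with `N >= 2`.
#' @return An `fs_dendro`.
#' @export
neighbor_joining <- function(dist) {
  stopifnot(inherits(dist, "fs_dist"))
  if (!is_complete(dist)) stopf("neighbor joining needs a complete matrix; impute first")
  n <- length(dist$ids)
  if (n < 2) stopf("need at least 2 entities")

  d <- dist$values
  nodes <- lapply(dist$ids, new_leaf)

  if (n == 2) {
    len <- d[1, 2] / 2
    root <- new_inner(nodes, c(len, len))
    return(new_dendro(root, dist$ids))
  }

  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    q[lower.tri(q)] <- Inf
    hits <- which(q == min(q), arr.ind = TRUE)
    pick <- hits[order(hits[, 1], hits[, 2])[1], ]        # smallest (i, j)
    i <- pick[[1]]; j <- pick[[2]]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    u <- new_inner(list(nodes[[i]], nodes[[j]]), c(bi, bj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nodes <- c(nodes[keep], list(u))
  }

  if (length(nodes) == 3) {
    b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    root <- new_inner(nodes, c(b1, b2, b3))
  } else {                                   # n was exactly 2 after joins
    root <- new_inner(nodes, c(d[1, 2] / 2, d[1, 2] / 2))
  }
  new_dendro(root, dist$ids)
}

#' Maximum-linkage subtree tessellation
#'
#' Recursive descent from the root: a subtree whose descendant leaves are all
#' within `t` of each other (in the ORIGINAL distances, not branch lengths)
#' is emitted as one cluster and the descent stops; otherwise its children
#' are visited. Single leaves always form singletons, so every entity is
#' assigned exactly once. Cluster labels (`c1`, `c2`, ...) follow depth-first
#' discovery order.
#'
#' @param tree An `fs_dendro`.
#' @param dist The `fs_dist` the tree was built from (or any matrix covering
#'   its leaves).
#' @param t Distance threshold (e.g. the ROC-optimal neighborhood size).
#' @return An `fs_partition`.
#' @export
max_linkage_clusters <- function(tree, dist, t) {
  stopifnot(inherits(tree, "fs_dendro"), inherits(dist, "fs_dist"))
  missing <- setdiff(tree$ids, dist$ids)
  if (length(missing)) stopf("tree leaves missing from distance matrix: %s",
                             paste(utils::head(missing, 5), collapse = ", "))
  d <- dist$values
  clusters <- list()
  descend <- function(node) {
    if (is_leaf(node)) {
      clusters[[length(clusters) + 1]] <<- node$leaf
      return(invisible())
    }
    lv <- node_leaves(node)
    sub <- d[lv, lv, drop = FALSE]
    if (max(sub) <= t) {
      clusters[[length(clusters) + 1]] <<- lv
    } else {
      for (ch in node$children) descend(ch)
    }
  }
  descend(tree$root)
  labels <- rep(paste0("c", seq_along(clusters)), lengths(clusters))
  partition(unlist(clusters, use.names = FALSE), labels)
}

#' Leaf-to-leaf path lengths of a dendrogram
#'
#' Sums branch lengths along the unique leaf-to-leaf paths. On a tree built
#' from additive distances this reproduces the input exactly, which makes it
#' the additivity oracle for [neighbor_joining()]. Computed through the
#' Newick serialization and `ape`, independently of the join bookkeeping.
#'
#' @param tree An `fs_dendro`.
#' @return A fully observed [distance_matrix()] over the leaf ids.
#' @export
tree_path_distances <- function(tree) {
  ph <- as_phylo(tree)
  cp <- stats::cophenetic(ph)
  cp <- cp[tree$ids, tree$ids]
  distance_matrix(cp, ids = tree$ids)
}

#' Convert a dendrogram to an ape "phylo" tree
#'
#' @param tree An `fs_dendro`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "fs_dendro"))
  ape::read.tree(text = newick_string(tree))
}
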
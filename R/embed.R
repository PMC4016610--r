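#' Double-center squared distances into an inner-product matrix
#'
#' Computes `A_ij = -1/2 (d2_ij - rowmean_i(d2) - colmean_j(d2) + grandmean(d2))`
#' where `d2` is the elementwise squared distance matrix. `A` is the Gram
#' matrix of any centered configuration realizing the distances; its rows sum
#' to zero.
#'
#' @param dist A complete [distance_matrix()]. Sparse matrices must be
#'   imputed first ([impute_missing()]).
#' @return A list with `values` (the centered matrix) and `ids`, of class
#'   `fs_gram`.
#' @export
double_center <- function(dist) {
  stopifnot(inherits(dist, "fs_dist"))
  if (!is_complete(dist)) {
    stopf("distance matrix has unobserved pairs; run impute_missing() first")
  }
  d2 <- dist$values^2
  rm <- rowMeans(d2)
  gm <- mean(d2)
  a <- -0.5 * (d2 - outer(rm, rm, `+`) + gm)
  a <- (a + t(a)) / 2
  structure(list(values = a, ids = dist$ids), class = "fs_gram")
}

# deterministic eigenvector orientation: largest-magnitude component positive
orient_columns <- function(v) {
  for (k in seq_len(ncol(v))) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  v
}

new_config <- function(ids, coords, method, dist = NULL, iterations = 0L,
                       eigenvalues = NULL, seed = NULL, weights = NULL) {
  coords <- as.matrix(coords)
  rownames(coords) <- ids
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  cfg <- structure(
    list(ids = ids, coords = coords, dim = ncol(coords), method = method,
         stress = NA_real_, iterations = as.integer(iterations),
         eigenvalues = eigenvalues, seed = seed),
    class = "fs_config"
  )
  if (!is.null(dist)) cfg$stress <- stress(cfg, dist, weights = weights)
  cfg
}

#' @export
print.fs_config <- function(x, ...) {
  cat(sprintf("<fs_config> %d entities in %dD (%s)%s%s\n",
              length(x$ids), x$dim, x$method,
              if (!is.na(x$stress)) sprintf(", stress %.6g", x$stress) else "",
              if (x$iterations > 0) sprintf(", %d iterations", x$iterations) else ""))
  invisible(x)
}

#' @export
as.matrix.fs_config <- function(x, ...) x$coords

#' Coordinates of a configuration as a tibble
#'
#' @param x An `fs_config` object.
#' @param ... Unused.
#' @return A tibble with `id` and one `dim<k>` column per axis.
#' @export
#' @exportS3Method generics::tidy
tidy.fs_config <- function(x, ...) {
  tibble::as_tibble(cbind(tibble::tibble(id = x$ids),
                          tibble::as_tibble(x$coords)))
}

#' One-row summary of a configuration
#'
#' @param x An `fs_config` object.
#' @param ... Unused.
#' @return A tibble with `method`, `n`, `dim`, `stress`, `iterations`.
#' @export
#' @exportS3Method generics::glance
glance.fs_config <- function(x, ...) {
  tibble::tibble(method = x$method, n = length(x$ids), dim = x$dim,
                 stress = x$stress, iterations = x$iterations)
}

#' Classical multidimensional scaling
#'
#' Eigendecomposition of the double-centered squared-distance matrix:
#' coordinates are `X_ik = sqrt(lambda_k) v_ik` for the `r` leading
#' eigenpairs. Columns whose eigenvalue is not strictly positive are set to
#' zero (negative eigenvalues flag triangle-inequality violations in the
#' input, which no Euclidean configuration can realize). The full eigenvalue
#' spectrum and the raw stress of the result are recorded.
#'
#' @param dist A complete [distance_matrix()].
#' @param r Target dimensionality, `1 <= r <= N - 1`.
#' @return An `fs_config` with `method = "cmds"`.
#' @export
classical_mds <- function(dist, r) {
  stopifnot(inherits(dist, "fs_dist"))
  n <- length(dist$ids)
  if (r < 1 || r >= n) stopf("need 1 <= r <= N-1 (got r = %s, N = %d)", r, n)
  a <- double_center(dist)
  e <- eigen(a$values, symmetric = TRUE)   # eigenvalues already non-increasing
  vec <- orient_columns(e$vectors[, seq_len(r), drop = FALSE])
  lam <- e$values[seq_len(r)]
  x <- vec %*% diag(sqrt(pmax(lam, 0)), nrow = r)
  x[, lam <= 0] <- 0
  new_config(dist$ids, x, "cmds", dist = dist, eigenvalues = e$values)
}

config_dist_matrix <- function(coords) {
  as.matrix(stats::dist(coords))
}

#' Raw stress of a configuration against target distances
#'
#' `sigma(X) = sum_{i<j} w_ij (d_ij(X) - delta_ij)^2`, with `d_ij(X)` the
#' Euclidean distance between rows of the coordinate matrix. By default
#' unobserved pairs of `dist` get weight 0.
#'
#' @param config An `fs_config`.
#' @param dist An `fs_dist` over the same ids.
#' @param weights Optional logical/numeric pair weight matrix; defaults to the
#'   observation mask of `dist`.
#' @return Non-negative scalar stress.
#' @export
stress <- function(config, dist, weights = NULL) {
  stopifnot(inherits(config, "fs_config"), inherits(dist, "fs_dist"))
  if (!identical(config$ids, dist$ids)) stopf("configuration and distance ids differ")
  w <- weights %||% dist$observed
  w <- w * 1
  d <- config_dist_matrix(config$coords)
  delta <- dist$values
  resid <- (d - delta)^2 * w
  resid[!dist$observed] <- 0
  sum(resid[upper.tri(resid)])
}

# Guttman-transform matrix B(X): b_ij = -w_ij * delta_ij / d_ij (i != j),
# zero when points coincide; diagonal = -rowsums.
guttman_b <- function(delta, dmat, w) {
  ratio <- ifelse(dmat > 0, delta / dmat, 0)
  b <- -w * ratio
  diag(b) <- 0
  diag(b) <- -rowSums(b)
  b
}

#' One SMACOF majorization update
#'
#' Complete case: the update
#' `x_i' = (1/N) sum_j (x_j + delta_ij (x_i - x_j)/||x_i - x_j||)`, with zero
#' contribution from the direction term for coincident points. With a weight
#' mask (sparse alignment sets) the exact weighted Guttman transform
#' `X' = V^+ B(X) X` is used, which reduces to the complete-case update when
#' every pair has weight one. Stress never increases under either form.
#'
#' @inheritParams stress
#' @param .vinv Optional precomputed pseudoinverse of the weighted Laplacian
#'   `V` (internal fast path for [smacof()]).
#' @return The updated `fs_config` with stress recomputed.
#' @export
smacof_update <- function(config, dist, weights = NULL, .vinv = NULL) {
  stopifnot(inherits(config, "fs_config"), inherits(dist, "fs_dist"))
  if (!identical(config$ids, dist$ids)) stopf("configuration and distance ids differ")
  n <- length(dist$ids)
  x <- config$coords
  dmat <- config_dist_matrix(x)
  delta <- dist$values
  if (is.null(weights) && is_complete(dist)) {
    # literal complete-case update; keeps the centroid of an uncentered start
    ratio <- ifelse(dmat > 0, delta / dmat, 0)
    diag(ratio) <- 0
    colsum <- matrix(colSums(x), n, ncol(x), byrow = TRUE)
    xnew <- (colsum + rowSums(ratio) * x - ratio %*% x) / n
  } else {
    w <- (weights %||% dist$observed) * 1
    diag(w) <- 0
    w[!dist$observed] <- 0
    delta0 <- delta
    delta0[!dist$observed] <- 0
    b <- guttman_b(delta0, dmat, w)
    vinv <- .vinv %||% {
      v <- -w
      diag(v) <- 0
      diag(v) <- -rowSums(v)
      MASS::ginv(v)
    }
    xnew <- vinv %*% (b %*% x)
  }
  out <- new_config(dist$ids, xnew, config$method, dist = dist,
                    iterations = config$iterations + 1L, seed = config$seed,
                    weights = weights)
  out$method <- config$method
  out
}

random_config <- function(ids, r, seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(ids)
  coords <- matrix(stats::runif(n * r, -scale, scale), n, r)
  new_config(ids, coords, "random", seed = seed)
}

#' SMACOF stress majorization
#'
#' Iterates [smacof_update()] from a classical-MDS, random, or user-supplied
#' start until the relative stress decrease `(s_prev - s_new)/s_prev` falls
#' below `tol` (default `1e-5`) or `max_iter` is reached. Sparse inputs run
#' the weighted Guttman transform with weight zero on unobserved pairs
#' (`missing = "weights"`, default), letting transitive relationships position
#' never-aligned pairs; alternatively the matrix is imputed first.
#'
#' @param dist An `fs_dist`.
#' @param r Target dimensionality.
#' @param init `"cmds"` (default), `"random"`, or an `fs_config` to refine.
#' @param tol Relative stress-change convergence threshold.
#' @param max_iter Iteration cap.
#' @param seed Seed for a random start.
#' @param missing Sparse handling: `"weights"`, `"impute-cap"`, `"impute-mean"`.
#' @return An `fs_config` with `method = "smacof"`, final stress and iteration
#'   count recorded.
#' @export
smacof <- function(dist, r, init = "cmds", tol = 1e-5, max_iter = 10000,
                   seed = NULL,
                   missing = c("weights", "impute-cap", "impute-mean")) {
  stopifnot(inherits(dist, "fs_dist"))
  missing <- match.arg(missing)
  n <- length(dist$ids)
  if (r < 1 || r >= n) stopf("need 1 <= r <= N-1 (got r = %s, N = %d)", r, n)

  weights <- NULL
  fit_dist <- dist
  if (!is_complete(dist)) {
    if (missing == "weights") {
      weights <- dist$observed * 1
      diag(weights) <- 0
    } else {
      fit_dist <- impute_missing(dist, sub("impute-", "", missing))
    }
  }

  cfg <- if (inherits(init, "fs_config")) {
    if (!identical(init$ids, dist$ids) || init$dim != r) {
      stopf("given initialization does not match ids/dimension")
    }
    init
  } else if (identical(init, "cmds")) {
    cmds_dist <- if (is_complete(dist)) dist else impute_missing(dist, if (is.null(dist$cap)) "mean" else "cap")
    classical_mds(cmds_dist, r)
  } else if (identical(init, "random")) {
    span <- max(fit_dist$values, na.rm = TRUE)
    random_config(dist$ids, r, seed = seed, scale = span / 2)
  } else {
    stopf("init must be 'cmds', 'random', or an fs_config")
  }

  vinv <- NULL
  if (!is.null(weights)) {
    v <- -weights
    diag(v) <- 0
    diag(v) <- -rowSums(v)
    vinv <- MASS::ginv(v)
  }

  cfg$method <- "smacof"
  cfg$iterations <- 0L
  cfg$seed <- if (identical(init, "random")) seed else NULL
  s_prev <- stress(cfg, fit_dist, weights = weights)
  cfg$stress <- s_prev
  if (!is.finite(tol) && tol > 0) return(cfg)   # degenerate tolerance: keep init
  if (s_prev == 0) return(cfg)
  for (it in seq_len(max_iter)) {
    cfg <- smacof_update(cfg, fit_dist, weights = weights, .vinv = vinv)
    s_new <- cfg$stress
    if (s_new == 0 || (s_prev - s_new) / s_prev < tol) break
    s_prev <- s_new
  }
  cfg
}

#' Euclidean distances of a configuration
#'
#' @param config An `fs_config`.
#' @return A fully observed [distance_matrix()] of the map distances.
#' @export
config_distances <- function(config) {
  stopifnot(inherits(config, "fs_config"))
  distance_matrix(config_dist_matrix(config$coords), ids = config$ids)
}

#' Procrustes statistic between two configurations
#'
#' Residual sum of squares after the optimal translation, rotation (reflection
#' allowed) and scaling of `b` onto `a`, normalized by the centered sum of
#' squares of `a`. 0 means a perfect similarity-transform match; values near 1
#' mean no linear correspondence.
#'
#' @param a,b `fs_config` objects over the same ids and dimension.
#' @return Scalar in `[0, 1]`.
#' @export
procrustes_statistic <- function(a, b) {
  stopifnot(inherits(a, "fs_config"), inherits(b, "fs_config"))
  if (!identical(a$ids, b$ids)) stopf("configurations have different ids")
  if (a$dim != b$dim) stopf("configurations have different dimensions")
  x <- scale(a$coords, center = TRUE, scale = FALSE)
  y <- scale(b$coords, center = TRUE, scale = FALSE)
  ssx <- sum(x^2)
  ssy <- sum(y^2)
  if (ssx == 0 || ssy == 0) return(if (ssx == ssy) 0 else 1)
  sv <- svd(crossprod(x, y))$d
  max(0, min(1, 1 - sum(sv)^2 / (ssx * ssy)))
}
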
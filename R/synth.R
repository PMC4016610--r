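# truncated Zipf sampler: P(k) proportional to k^-exponent, k = 1..max
rzipf <- function(n, exponent, max) {
  k <- seq_len(max)
  sample(k, n, replace = TRUE, prob = k^(-exponent))
}

draw_sizes <- function(n, spec) {
  if (is.numeric(spec) && length(spec) == 1) return(rep(as.integer(spec), n))
  stopifnot(is.list(spec), !is.null(spec$type))
  switch(spec$type,
    fixed = rep(as.integer(spec$value), n),
    zipf = rzipf(n, spec$exponent %||% 1.5, spec$max %||% 100),
    stopf("unknown size distribution type '%s'", spec$type)
  )
}

#' Parameters for the synthetic structure-space generator
#'
#' Defaults describe a hierarchical point cloud loosely shaped like a curated
#' fold classification: a modest number of folds, a skewed (Zipf,
#' singleton-heavy) number of superfamilies per fold and members per
#' superfamily, and nested isotropic Gaussian spreads
#' `fold_scale > superfamily_scale > member_scale` so that clades are
#' separable by construction.
#'
#' @param r_true Generative dimensionality.
#' @param n_folds Number of fold centers.
#' @param superfamilies_per_fold Size spec: a fixed integer, or
#'   `list(type = "zipf", exponent, max)`.
#' @param members_per_superfamily Size spec, same forms; singletons allowed.
#' @param fold_scale,superfamily_scale,member_scale Isotropic Gaussian sd of
#'   fold centers around the origin, superfamily centers around their fold,
#'   and members around their superfamily.
#' @param noise_sd Additive Gaussian noise sd applied to pairwise distances.
#' @param sparsity_fraction Target observed-pair fraction in `(0, 1]`.
#' @param seed Master seed; all stages draw from named substreams of it.
#' @return A list of class `fs_synth_params`.
#' @export
synth_params <- function(r_true = 12,
                         n_folds = 15,
                         superfamilies_per_fold = list(type = "zipf", exponent = 1.5, max = 10),
                         members_per_superfamily = list(type = "zipf", exponent = 1.5, max = 100),
                         fold_scale = 10,
                         superfamily_scale = 3,
                         member_scale = 1,
                         noise_sd = 0.5,
                         sparsity_fraction = 1,
                         seed = 1L) {
  stopifnot(r_true >= 1, n_folds >= 1, fold_scale > 0, superfamily_scale > 0,
            member_scale > 0, noise_sd >= 0,
            sparsity_fraction > 0, sparsity_fraction <= 1)
  structure(
    list(r_true = r_true, n_folds = n_folds,
         superfamilies_per_fold = superfamilies_per_fold,
         members_per_superfamily = members_per_superfamily,
         fold_scale = fold_scale, superfamily_scale = superfamily_scale,
         member_scale = member_scale, noise_sd = noise_sd,
         sparsity_fraction = sparsity_fraction, seed = as.integer(seed)),
    class = "fs_synth_params"
  )
}

#' Generate a clade-structured synthetic structure space
#'
#' Draws fold centers from `N(0, fold_scale^2 I)` in `r_true` dimensions,
#' superfamily centers around their fold, members around their superfamily;
#' assigns synthetic codes `c1.f<i>.s<j>.m<k>`; and computes the exact
#' Euclidean distance matrix, optionally perturbed with additive distance
#' noise ([perturb_distances()]) and sparsified with a scale-free mask
#' ([sparsify()]) per the parameters. Fully reproducible from the seed.
#'
#' @param params An [synth_params()] object.
#' @return An `fs_synth_space`: `coords_true` (an `fs_config`),
#'   `classification` (an `fs_classification`), `distances` (`fs_dist`,
#'   noise/sparsity applied), `distances_exact` (noise-free, complete), and
#'   `params`.
#' @export
generate_space <- function(params = synth_params()) {
  stopifnot(inherits(params, "fs_synth_params"))
  set.seed(substream_seed(params$seed, "hierarchy"))
  r <- params$r_true

  n_sf <- draw_sizes(params$n_folds, params$superfamilies_per_fold)
  ids <- character(0); codes <- character(0)
  centers <- list()
  for (f in seq_len(params$n_folds)) {
    fc <- stats::rnorm(r, 0, params$fold_scale)
    if (n_sf[f] < 1) next
    n_mem <- draw_sizes(n_sf[f], params$members_per_superfamily)
    for (s in seq_len(n_sf[f])) {
      sc <- fc + stats::rnorm(r, 0, params$superfamily_scale)
      for (m in seq_len(n_mem[s])) {
        centers[[length(centers) + 1]] <- sc + stats::rnorm(r, 0, params$member_scale)
        ids <- c(ids, sprintf("f%d_s%d_m%d", f, s, m))
        codes <- c(codes, sprintf("c1.f%d.s%d.m%d", f, s, m))
      }
    }
  }
  coords <- do.call(rbind, centers)
  cls <- classification_table(ids, codes)
  cfg <- new_config(ids, coords, "generator")

  exact <- config_distances(cfg)
  d <- exact
  if (params$noise_sd > 0) {
    d <- perturb_distances(d, noise_sd = params$noise_sd, violation_rate = 0,
                           seed = substream_seed(params$seed, "noise"))
  }
  if (params$sparsity_fraction < 1) {
    d <- sparsify(d, fraction = params$sparsity_fraction,
                  seed = substream_seed(params$seed, "mask"))
  }
  structure(
    list(coords_true = cfg, classification = cls, distances = d,
         distances_exact = exact, params = params),
    class = "fs_synth_space"
  )
}

#' @export
print.fs_synth_space <- function(x, ...) {
  sf <- length(unique(sccs_prefix(x$classification$sccs, 3)))
  cat(sprintf("<fs_synth_space> %d members, %d folds, %d superfamilies, r_true = %d\n",
              length(x$coords_true$ids), x$params$n_folds, sf, x$params$r_true))
  invisible(x)
}

#' Perturb a distance matrix with noise and triangle violations
#'
#' Adds independent Gaussian noise (sd `noise_sd`) to each unordered pair,
#' clamped at zero, and multiplicatively inflates a `violation_rate` fraction
#' of pairs (factor 1.5-3) so that the perturbed matrix violates the triangle
#' inequality — detectable downstream as negative eigenvalues of the
#' double-centered matrix.
#'
#' @param dist An `fs_dist`.
#' @param noise_sd Gaussian sd of the additive distance noise.
#' @param violation_rate Fraction of pairs to inflate, in `[0, 1]`.
#' @param seed Optional seed.
#' @return A perturbed `fs_dist` with the same observation mask.
#' @export
perturb_distances <- function(dist, noise_sd = 0, violation_rate = 0, seed = NULL) {
  stopifnot(inherits(dist, "fs_dist"), noise_sd >= 0,
            violation_rate >= 0, violation_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- dist$values
  n <- nrow(v)
  ut <- upper.tri(v)
  m <- sum(ut)
  if (noise_sd > 0) {
    eps <- stats::rnorm(m, 0, noise_sd)
    v[ut] <- pmax(0, v[ut] + eps)
  }
  if (violation_rate > 0) {
    hit <- stats::runif(m) < violation_rate
    v[ut][hit] <- v[ut][hit] * stats::runif(sum(hit), 1.5, 3)
  }
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- 0
  v[!dist$observed] <- NA_real_
  distance_matrix(v, ids = dist$ids, observed = dist$observed, cap = dist$cap)
}

#' Scale-free sparsification of a distance matrix
#'
#' Assigns each entity a heavy-tailed (Pareto) weight and keeps each pair
#' with probability proportional to the product of its endpoint weights,
#' rescaled (probabilities capped at 1) so the expected observed fraction
#' matches `fraction`. The resulting observed-degree histogram follows an
#' approximate power law, emulating an aligner whose completed alignments
#' are mediated by a few hub structures. Connectivity of the observed graph
#' is checked; a disconnected mask is flagged with a warning (embedding a
#' disconnected graph is ill-posed).
#'
#' @param dist An `fs_dist`.
#' @param fraction Target observed fraction in `(0, 1]`.
#' @param hub_exponent Pareto shape of the entity weights (smaller = heavier
#'   hubs); default 1.5.
#' @param seed Optional seed.
#' @return An `fs_dist` with an updated mask; attribute `fs_connected` is
#'   `TRUE`/`FALSE`.
#' @export
sparsify <- function(dist, fraction, hub_exponent = 1.5, seed = NULL) {
  stopifnot(inherits(dist, "fs_dist"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(dist)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dist$ids)
  w <- stats::runif(n)^(-1 / hub_exponent)       # Pareto(shape = hub_exponent)
  pw <- outer(w, w)
  ut <- upper.tri(pw)
  raw <- pw[ut]
  # scale c so that mean(pmin(c * raw, 1)) == fraction, respecting the cap
  f <- function(cc) mean(pmin(cc * raw, 1)) - fraction
  cc <- stats::uniroot(f, lower = 0, upper = 1 / min(raw), tol = 1e-12)$root
  p <- pmin(cc * raw, 1)
  keep <- stats::runif(length(raw)) < p
  obs <- matrix(FALSE, n, n)
  obs[ut][keep] <- TRUE
  obs <- obs | t(obs)
  diag(obs) <- TRUE
  obs <- obs & dist$observed
  out <- distance_matrix(dist$values, ids = dist$ids, observed = obs,
                         cap = dist$cap)
  connected <- observed_graph_connected(obs)
  if (!connected) {
    warning("observed alignment graph is disconnected; weighted embedding is ill-posed",
            call. = FALSE)
  }
  attr(out, "fs_connected") <- connected
  out
}

#' Restrict a sparse distance matrix to its largest connected component
#'
#' A disconnected observed-alignment graph leaves relative positions of the
#' components unconstrained, making any embedding ill-posed; analyses of very
#' sparse masks are therefore run on the giant component.
#'
#' @param dist An `fs_dist`.
#' @return The `fs_dist` restricted to the largest component's ids (input
#'   returned unchanged when already connected).
#' @export
largest_component <- function(dist) {
  stopifnot(inherits(dist, "fs_dist"))
  g <- dist$observed
  diag(g) <- FALSE
  n <- nrow(g)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(g[i, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  if (cur == 1L) return(dist)
  big <- which.max(tabulate(comp))
  dist_subset(dist, dist$ids[comp == big])
}

# connectivity of the observed off-diagonal graph by breadth-first search
observed_graph_connected <- function(obs) {
  n <- nrow(obs)
  if (n <= 1) return(TRUE)
  g <- obs
  diag(g) <- FALSE
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(g[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Per-entity observed-partner counts
#'
#' @param dist An `fs_dist`.
#' @return Named integer vector: number of observed off-diagonal partners of
#'   each entity (input to [degree_powerlaw_fit()]).
#' @export
observed_degrees <- function(dist) {
  stopifnot(inherits(dist, "fs_dist"))
  obs <- dist$observed
  diag(obs) <- FALSE
  stats::setNames(rowSums(obs), dist$ids)
}
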
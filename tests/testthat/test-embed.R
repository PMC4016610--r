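test_that("double centering reproduces the hand-computed Gram matrix", {
  a <- double_center(mk_dist(matrix(c(0, 1, 1, 0), 2, 2)))
  expect_equal(a$values, matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b"))))
  z <- double_center(mk_dist(matrix(0, 3, 3)))
  expect_true(all(z$values == 0))
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:40, 1)
    d <- coords_dist(matrix(stats::rnorm(n * 3), n, 3), ids = paste0("p", 1:n))
    a <- double_center(d)
    expect_equal(a$values, t(a$values))
    expect_lt(max(abs(rowSums(a$values))), 1e-9 * n * max(abs(a$values)))
  }
  sparse <- mk_dist(matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3))
  expect_error(double_center(sparse), "impute_missing")
})

test_that("classical scaling recovers Euclidean-realizable distances exactly", {
  # collinear points on a line need only one dimension
  d <- coords_dist(matrix(c(0, 3, 7), 3, 1))
  cfg <- classical_mds(d, 1)
  expect_lt(max(abs(config_distances(cfg)$values - d$values)), 1e-9)
  # equilateral triangle is exactly planar
  tri <- mk_dist(matrix(1, 3, 3) - diag(3))
  c2 <- classical_mds(tri, 2)
  got <- config_distances(c2)$values
  expect_equal(got[upper.tri(got)], rep(1, 3), tolerance = 1e-12)
  # full exactness sweep: any point set in dimension q <= r is recovered
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:60, 1)
    q <- sample(1:6, 1)
    x <- matrix(stats::rnorm(n * q, sd = 3), n, q)
    d <- coords_dist(x, ids = paste0("p", 1:n))
    r <- min(q + sample(0:3, 1), n - 1)
    cfg <- classical_mds(d, r)
    expect_lt(max(abs(config_distances(cfg)$values - d$values)), 1e-8)
    gen <- foldspace:::new_config(d$ids, cbind(x, matrix(0, n, r - q)), "generator")
    expect_lt(procrustes_statistic(gen, cfg), 1e-8)
  }
  expect_error(classical_mds(d, nrow(as.matrix(d))), "N-1")
})

test_that("triangle-inequality violations surface as zeroed negative-eigenvalue axes", {
  viol <- mk_dist(matrix(c(0, 1, 1, 1, 0, 3, 1, 3, 0), 3, 3))
  cfg <- classical_mds(viol, 2)
  expect_lt(min(cfg$eigenvalues), 0)
  neg <- which(cfg$eigenvalues[1:2] <= 0)
  expect_true(length(neg) > 0 && all(cfg$coords[, neg] == 0))
  # rank property: strictly positive eigenvalues = affine rank of the generator
  for (q in 1:3) {
    set.seed(q)
    x <- matrix(stats::rnorm(12 * q), 12, q)
    cfg <- classical_mds(coords_dist(x, ids = paste0("p", 1:12)), 5)
    expect_equal(sum(cfg$eigenvalues > 1e-8 * max(cfg$eigenvalues)), q)
  }
})

test_that("stress is the weighted squared deviation and is rigid-motion invariant", {
  x <- matrix(stats::rnorm(10 * 2, sd = 2), 10, 2)
  d <- coords_dist(x, ids = paste0("p", 1:10))
  cfg <- foldspace:::new_config(d$ids, x, "given")
  expect_equal(stress(cfg, d), 0)
  # two points embedded at distance 1 with target 3 -> (1-3)^2 = 4
  cfg2 <- foldspace:::new_config(c("a", "b"), matrix(c(0, 1), 2, 1), "given")
  expect_equal(stress(cfg2, mk_dist(matrix(c(0, 3, 3, 0), 2, 2))), 4)
  # rotation + translation leave stress unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- foldspace:::new_config(d$ids, sweep(x %*% rot, 2, c(5, -2), `+`), "given")
  set.seed(1)
  target <- perturb_distances(d, noise_sd = 0.3, seed = 1)
  expect_equal(stress(cfg, target), stress(moved, target), tolerance = 1e-9)
  expect_error(stress(cfg2, d), "ids differ")
})

test_that("the majorization update matches the two-point oracle and never raises stress", {
  d <- mk_dist(matrix(c(0, 3, 3, 0), 2, 2))
  cfg <- foldspace:::new_config(c("a", "b"), matrix(c(0, 1), 2, 1), "given")
  up <- smacof_update(cfg, d)
  expect_equal(unname(up$coords[, 1]), c(-1, 2))   # hand evaluation of the update
  expect_equal(up$stress, 0)
  # a zero-stress configuration is a fixed point
  again <- smacof_update(up, d)
  expect_equal(again$coords, up$coords, tolerance = 1e-12)
  # monotone stress on random instances, every iteration, both modes
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:25, 1)
    d <- coords_dist(matrix(stats::rnorm(n * 5), n, 5), ids = paste0("p", 1:n))
    d <- perturb_distances(d, noise_sd = 0.4, violation_rate = 0.05, seed = seed)
    w <- if (seed %% 2 == 0) {
      wm <- matrix(stats::runif(n * n) < 0.8, n, n)
      wm <- wm | t(wm); diag(wm) <- FALSE
      wm * 1
    } else NULL
    cfg <- foldspace:::random_config(d$ids, 2, seed = seed, scale = 3)
    s <- stress(cfg, d, weights = w)
    for (it in 1:15) {
      cfg <- smacof_update(cfg, d, weights = w)
      s_new <- stress(cfg, d, weights = w)
      expect_lte(s_new, s + 1e-9)
      s <- s_new
    }
  }
})

test_that("SMACOF converges from both initializations to the same map", {
  sq <- coords_dist(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE))
  a <- smacof(sq, 2, init = "cmds")
  expect_lt(a$stress, 1e-10)
  expect_lte(a$iterations, 2)
  b <- smacof(sq, 2, init = "random", seed = 3, tol = 1e-12)
  expect_lt(abs(a$stress - b$stress), 1e-6)
  expect_lt(procrustes_statistic(a, b), 1e-3)
  # degenerate tolerance returns the initialization untouched
  frozen <- smacof(sq, 2, init = "random", seed = 7, tol = Inf)
  expect_identical(frozen$iterations, 0L)
  expect_equal(frozen$coords, foldspace:::random_config(sq$ids, 2, seed = 7,
                                                        scale = max(sq$values) / 2)$coords)
})

test_that("imputation fills unobserved pairs with cap or mean", {
  full <- mk_dist(matrix(c(0, 2, 2, 0), 2, 2))
  expect_identical(impute_missing(full, "mean"), full)
  m <- matrix(c(0, 2, NA, 2, 0, 4, NA, 4, 0), 3, 3)
  sparse <- distance_matrix(m, ids = c("a", "b", "c"), cap = 10)
  capped <- impute_missing(sparse, "cap")
  expect_equal(capped$values["a", "c"], 10)
  expect_equal(capped$values["c", "a"], 10)
  expect_true(all(capped$observed))
  meaned <- impute_missing(sparse, "mean")
  expect_equal(meaned$values["a", "c"], 3)      # mean of observed {2, 4}
  nocap <- distance_matrix(m, ids = c("a", "b", "c"))
  expect_error(impute_missing(nocap, "cap"), "cap")
})

test_that("configuration distances are Euclidean, symmetric, and metric", {
  single <- foldspace:::new_config("a", matrix(0, 1, 1), "given")
  expect_equal(config_distances(single)$values, matrix(0, 1, 1, dimnames = list("a", "a")))
  two <- foldspace:::new_config(c("a", "b"), matrix(c(0, 3, 0, 4), 2, 2), "given")
  expect_equal(config_distances(two)$values["a", "b"], 5)
  set.seed(3)
  x <- matrix(stats::rnorm(50 * 3), 50, 3)
  d <- config_distances(foldspace:::new_config(paste0("p", 1:50), x, "given"))$values
  expect_equal(d, t(d))
  for (i in 1:10) {
    trip <- sample(50, 3)
    expect_lte(d[trip[1], trip[3]],
               d[trip[1], trip[2]] + d[trip[2], trip[3]] + 1e-12)
  }
})

test_that("Procrustes statistic is zero under similarity transforms and matches vegan", {
  set.seed(11)
  x <- matrix(stats::rnorm(20 * 3), 20, 3)
  a <- foldspace:::new_config(paste0("p", 1:20), x, "given")
  expect_equal(procrustes_statistic(a, a), 0)
  th <- 1.1
  rot <- diag(3); rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- foldspace:::new_config(a$ids, sweep(2 * x %*% rot, 2, c(1, -4, 2), `+`), "given")
  expect_lt(procrustes_statistic(a, b), 1e-12)
  # unrelated random configuration: statistic large
  set.seed(12)
  rnd <- foldspace:::new_config(a$ids, matrix(stats::rnorm(20 * 3), 20, 3), "given")
  expect_gt(procrustes_statistic(a, rnd), 0.5)
  # cross-check against vegan's symmetric procrustes residual
  v <- vegan::procrustes(a$coords, rnd$coords, symmetric = TRUE)
  expect_equal(procrustes_statistic(a, rnd), v$ss, tolerance = 1e-9)
  expect_error(procrustes_statistic(a, foldspace:::new_config(a$ids, x[, 1:2], "given")),
               "dimensions")
})
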
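test_that("percentile index follows the nearest-rank formula with clamping", {
  # n = round_half_up(p/100 * (M + 1)), M = N(N-1)/2
  expect_identical(percentile_index(99.95, 3967), 7862629L)
  expect_identical(percentile_index(50, 5), 6L)        # 0.5 * 11 = 5.5, half-up
  expect_identical(percentile_index(0, 5), 1L)         # clamped to lower bound
  expect_identical(percentile_index(100, 5), 10L)      # never exceeds #pairs
  for (n in c(2, 3, 10, 57)) {
    expect_identical(percentile_index(100, n), as.integer(n * (n - 1) / 2))
  }
  expect_error(percentile_index(50, 1), "at least 2")
  expect_error(percentile_index(101, 5), "\\[0, 100\\]")
})

test_that("cap selection matches a brute-force sort-and-index oracle", {
  m <- matrix(0, 5, 5)
  m[upper.tri(m)] <- 1:10
  sim <- mk_sim(m + t(m))
  expect_equal(select_max_score(sim, 100), 10)
  expect_equal(select_max_score(sim, 50), 6)            # n = round(0.5 * 11)
  const <- mk_sim(matrix(7, 4, 4))
  for (p in c(0, 13.7, 50, 99.95, 100)) {
    expect_equal(select_max_score(const, p), 7)
  }
  # randomized agreement with the oracle, including large lists
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(c(5, 20, 142), 1)
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- round(stats::rnorm(n * (n - 1) / 2, 50, 20), 3)
    sim <- mk_sim(v + t(v), ids = paste0("s", 1:n))
    p <- stats::runif(1, 0, 100)
    scores <- sort(v[upper.tri(v)])
    oracle <- scores[min(max(round(floor(p / 100 * (length(scores) + 1) + 0.5)), 1),
                         length(scores))]
    expect_equal(select_max_score(sim, p), oracle)
  }
  empty <- mk_sim(matrix(NA_real_, 3, 3))
  expect_error(select_max_score(empty), "no observed")
})

test_that("similarity-to-distance transform caps, clamps, and preserves masks", {
  m <- matrix(0, 5, 5)
  m[upper.tri(m)] <- c(3, 1, 2, 4, 5, 6, 7, 8, 9, 12)
  sim <- mk_sim(m + t(m))
  d <- similarity_to_distance(sim, p = 85)              # n = round(0.85*11) = 9 -> s_n = 9
  expect_equal(d$cap, 9)
  expect_equal(d$values["a", "b"], 9 - 3)               # delta = s_n - s_ij
  expect_true(all(diag(d$values) == 0))
  # scores above the cap: clamp -> 0, literal -> s_n
  over <- which(m + t(m) >= 9 & upper.tri(m), arr.ind = TRUE)
  expect_true(all(d$values[over] == 0))
  lit <- similarity_to_distance(sim, p = 85, overflow_mode = "literal")
  expect_true(all(lit$values[over] == 9))
  # unobserved stays unobserved
  m2 <- m + t(m)
  m2[1, 3] <- m2[3, 1] <- NA
  sim2 <- mk_sim(m2)
  d2 <- similarity_to_distance(sim2, p = 100)
  expect_false(d2$observed[1, 3])
  expect_true(is.na(d2$values[1, 3]))
  # refusal contracts
  dis <- mk_sim(matrix(c(0, 1, 1, 0), 2, 2), polarity = "dissimilarity")
  expect_error(similarity_to_distance(dis), "passthrough_dissimilarity")
  asym <- mk_sim(matrix(c(0, 4, 6, 0), 2, 2))
  expect_error(similarity_to_distance(asym), "symmetrize")
})

test_that("capped distances stay in [0, s_n], symmetric, monotone in score", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:30, 1)
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- stats::runif(n * (n - 1) / 2, 0, 30)
    sim <- mk_sim(v + t(v), ids = paste0("s", 1:n))
    p <- stats::runif(1, 10, 100)
    d <- similarity_to_distance(sim, p = p)
    up <- d$values[upper.tri(d$values)]
    expect_true(all(up >= 0 & up <= d$cap))
    expect_identical(d$values, t(d$values))
    expect_true(all(diag(d$values) == 0))
    # monotonicity below the cap: larger similarity, smaller distance
    s_up <- sim$values[upper.tri(sim$values)]
    below <- s_up < d$cap
    ord <- order(s_up[below])
    expect_true(all(diff(up[below][ord]) <= 0))
  }
})

test_that("dissimilarity passthrough copies values and rejects negatives", {
  m <- matrix(c(0, 2, 2, 0), 2, 2)
  sim <- mk_sim(m, polarity = "dissimilarity")
  d <- passthrough_dissimilarity(sim)
  expect_equal(d$values, sim$values)
  expect_null(d$cap)
  # nonzero diagonal is forced to zero, off-diagonals untouched
  m2 <- matrix(c(5, 2, 2, 5), 2, 2)
  d2 <- passthrough_dissimilarity(mk_sim(m2, polarity = "dissimilarity"))
  expect_equal(diag(d2$values), c(a = 0, b = 0))
  expect_equal(d2$values[1, 2], 2)
  expect_error(passthrough_dissimilarity(
    mk_sim(matrix(c(0, -1, -1, 0), 2, 2), polarity = "dissimilarity")),
    "negative")
  expect_error(passthrough_dissimilarity(mk_sim(m)), "similarity_to_distance")
})

test_that("symmetrization combines two-way scores and copies one-way scores", {
  m <- matrix(c(0, 4, NA, 6, 0, 3, NA, NA, 0), 3, 3, byrow = TRUE)
  sim <- mk_sim(m)
  for (rule in c("mean", "min", "max")) {
    s <- symmetrize(sim, rule)
    want <- switch(rule, mean = 5, min = 4, max = 6)
    expect_equal(s$values["a", "b"], want)
    expect_equal(s$values["b", "a"], want)
    expect_equal(s$values["b", "c"], 3)   # one-directional copy
    expect_equal(s$values["c", "b"], 3)
    expect_false(s$observed["a", "c"])
  }
  already <- mk_sim(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(symmetrize(already)$values, already$values)
})
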
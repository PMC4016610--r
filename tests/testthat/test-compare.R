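test_that("Jaccard coefficient behaves as a set similarity", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_error(jaccard(character(0), character(0)), "undefined")
  # symmetry and the metric property of 1 - J on small random universes
  universe <- letters[1:6]
  set.seed(5)
  sets <- replicate(12, sample(universe, sample(1:6, 1)), simplify = FALSE)
  for (k in 1:30) {
    abc <- sample(sets, 3)
    expect_equal(jaccard(abc[[1]], abc[[2]]), jaccard(abc[[2]], abc[[1]]))
    d12 <- 1 - jaccard(abc[[1]], abc[[2]])
    d23 <- 1 - jaccard(abc[[2]], abc[[3]])
    d13 <- 1 - jaccard(abc[[1]], abc[[3]])
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("best-match mapping maximizes J with deterministic ties", {
  src <- partition(as.character(1:4), c("A", "A", "B", "C"))
  tgt <- partition(as.character(1:4), c("X", "X", "X", "Y"))
  map <- best_match_mapping(src, tgt)
  expect_equal(map$target[map$source == "A"], "X")
  expect_equal(map$jaccard[map$source == "A"], 2 / 3)
  expect_equal(map$target[map$source == "B"], "X")
  expect_equal(map$jaccard[map$source == "B"], 1 / 3)
  expect_equal(map$target[map$source == "C"], "Y")
  # identical partitions map onto themselves with J = 1
  self <- best_match_mapping(src, src)
  expect_true(all(self$jaccard == 1))
  expect_equal(self$target, self$source)
  # equal-J ties resolve to the lexicographically smaller target label
  s2 <- partition(c("1", "2"), c("G", "G"))
  t2 <- partition(c("1", "2"), c("zzz", "aaa"))
  expect_equal(best_match_mapping(s2, t2)$target, "aaa")
  # a source sharing no entity is flagged with J = 0
  s3 <- partition(c("1", "9"), c("A", "Lone"))
  t3 <- partition(c("1", "8"), c("X", "Y"))
  m3 <- best_match_mapping(s3, t3)
  expect_true(m3$unmatched[m3$source == "Lone"])
  expect_equal(m3$jaccard[m3$source == "Lone"], 0)
})

test_that("mapping statistics satisfy the degree identities", {
  src <- partition(as.character(1:4), c("A", "A", "B", "C"))
  tgt <- partition(as.character(1:4), c("X", "X", "X", "Y"))
  st <- mapping_stats(src, tgt)
  expect_equal(st$max_degree, 2L)                         # X used twice
  expect_equal(st$mean_degree, 1.5)
  expect_equal(st$ratio_minus_1, 0.5)
  expect_equal(st$mean_sim, (2 / 3 + 1 / 3 + 1) / 3)
  expect_equal(st$std_degree, 0.5)                        # population sd of {2, 1}
  ident <- mapping_stats(src, src)
  expect_equal(ident$max_degree, 1L)
  expect_equal(ident$mean_degree, 1)
  expect_equal(ident$std_degree, 0)
  expect_equal(ident$mean_sim, 1)
  expect_equal(ident$ratio_minus_1, 0)
  # mean_degree * n_unique_targets == n_source on random partitions
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(20:60, 1)
    a <- partition(paste0("e", 1:n), paste0("s", sample(8, n, TRUE)))
    b <- partition(paste0("e", 1:n), paste0("t", sample(5, n, TRUE)))
    st <- mapping_stats(a, b)
    expect_equal(st$mean_degree * st$n_unique_targets, st$n_source)
    expect_equal(st$ratio_minus_1, st$mean_degree - 1)
    # directionality: both directions are legitimate, distinct summaries
    expect_s3_class(mapping_stats(b, a), "fs_mapping_stats")
  }
})

test_that("the printed source:target ratios reproduce their mean degrees", {
  # a clade system divided across clusters: singleton sources grouped by
  # target blocks reproduce the published count ratios exactly
  ratio_case <- function(n_source, n_target) {
    sizes <- rep(n_source %/% n_target, n_target)
    sizes[seq_len(n_source %% n_target)] <- sizes[seq_len(n_source %% n_target)] + 1
    ids <- paste0("e", seq_len(sum(sizes)))
    src <- partition(ids, paste0("s", seq_along(ids)))          # singletons
    tgt <- partition(ids, rep(paste0("t", seq_along(sizes)), sizes))
    mapping_stats(src, tgt)
  }
  t7 <- ratio_case(1180, 612)    # superfamily table, probability-score row
  expect_equal(round(t7$mean_degree, 3), 1.928)
  expect_equal(round(t7$ratio_minus_1, 3), 0.928)
  expect_equal(t7$n_source, 1180L)
  expect_equal(t7$n_unique_targets, 612L)
  t8 <- ratio_case(757, 487)     # fold table, probability-score row
  expect_equal(round(t8$mean_degree, 3), 1.554)
  expect_equal(round(t8$ratio_minus_1, 3), 0.554)
  t8b <- ratio_case(757, 385)
  expect_equal(round(t8b$mean_degree, 3), 1.966)
  inv <- ratio_case(422, 390)    # inverse-direction row
  expect_equal(round(inv$mean_degree, 3), 1.082)
  expect_equal(round(inv$ratio_minus_1, 3), 0.082)
})

test_that("power-law fitting recovers exact, flat, and sampled laws", {
  # frequencies exactly C * x^-2 at bin centers 1, 2, 4, 8 (8 equal-width bins)
  counts <- c(0.5, rep(1, 255), rep(2, 64), rep(4, 16), rep(8, 3), 8.5)
  fit <- degree_powerlaw_fit(counts, n_bins = 8)
  expect_equal(fit$exponent, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$bins, 4)
  # uniform frequencies: slope 0 (two integer values per bin, none on breaks)
  flat <- degree_powerlaw_fit(rep(1:10, each = 7), n_bins = 5)
  expect_equal(flat$exponent, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 1)
  # heavy-tailed sample: clearly negative slope, tight fit (seeded)
  set.seed(31)
  pareto <- floor(stats::runif(4000)^(-1 / 1.2))
  samp <- degree_powerlaw_fit(pareto[pareto <= 500], n_bins = 25)
  expect_lt(samp$exponent, -0.8)
  expect_gt(samp$r_squared, 0.8)
  expect_error(degree_powerlaw_fit(rep(3, 10)), "degenerate")
  expect_error(degree_powerlaw_fit(c(1, 2), n_bins = 2), "non-empty")
})
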
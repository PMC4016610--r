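#' Jaccard coefficient of two id sets
#'
#' `|A intersect B| / |A union B|`.
#'
#' @param a,b Character vectors (treated as sets).
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stopf("Jaccard of two empty sets is undefined")
  length(intersect(a, b)) / u
}

#' Best-match mapping between two partitions
#'
#' Maps every source group to the target group maximizing the Jaccard
#' coefficient of their member sets, breaking ties by the lexicographically
#' smallest target label. A source group sharing no entity with any target
#' group maps to `NA` with `jaccard = 0` (flagged `unmatched`).
#'
#' @param source,target `fs_partition` objects over overlapping entity sets.
#' @return Tibble `source`, `target`, `jaccard`, `unmatched`.
#' @export
best_match_mapping <- function(source, target) {
  stopifnot(inherits(source, "fs_partition"), inherits(target, "fs_partition"))
  src <- partition_sets(source)
  tgt <- partition_sets(target)
  if (!length(intersect(source$id, target$id))) {
    stopf("partitions share no entities")
  }
  tlab <- sort(names(tgt))
  rows <- lapply(sort(names(src)), function(s) {
    js <- vapply(tlab, function(tn) jaccard(src[[s]], tgt[[tn]]), numeric(1))
    best <- which.max(js)    # first max = smallest label (tlab sorted)
    if (js[best] == 0) {
      tibble::tibble(source = s, target = NA_character_, jaccard = 0,
                     unmatched = TRUE)
    } else {
      tibble::tibble(source = s, target = tlab[best], jaccard = unname(js[best]),
                     unmatched = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Directional partition-agreement statistics
#'
#' Summarizes the [best_match_mapping()] of `source` onto `target`: the
#' degree of each used target (how many source groups best-match it), its
#' max / mean / population-sd; the mean and population-sd of the best-match
#' Jaccard coefficients; and `ratio_minus_1 = n_source / n_unique_targets - 1`
#' (0 means a one-to-one correspondence). `mean_degree` equals
#' `n_source / n_unique_targets` exactly. The statistic is directional:
#' report both directions to see fragmentation both ways.
#'
#' @inheritParams best_match_mapping
#' @param direction Optional 2-character label, e.g. `c("scop", "clusters")`.
#' @return A one-row `fs_mapping_stats` tibble.
#' @export
mapping_stats <- function(source, target, direction = c("source", "target")) {
  map <- best_match_mapping(source, target)
  matched <- map[!map$unmatched, ]
  deg <- as.integer(table(matched$target))
  n_source <- nrow(map)
  n_unique <- length(unique(matched$target))
  out <- tibble::tibble(
    direction = paste(direction, collapse = "-"),
    max_degree = if (length(deg)) max(deg) else NA_integer_,
    mean_degree = n_source / n_unique,
    std_degree = if (length(deg)) pop_sd(deg) else NA_real_,
    mean_sim = mean(map$jaccard),
    std_sim = pop_sd(map$jaccard),
    n_source = n_source,
    n_unique_targets = n_unique,
    ratio_minus_1 = n_source / n_unique - 1
  )
  class(out) <- c("fs_mapping_stats", class(out))
  attr(out, "mapping") <- map
  out
}

#' Bidirectional partition comparison
#'
#' @inheritParams best_match_mapping
#' @param names Labels for the two partitions in the `direction` column.
#' @return Two-row tibble: `source -> target` and `target -> source` stats.
#' @export
compare_partitions <- function(source, target, names = c("clusters", "clades")) {
  dplyr::bind_rows(
    mapping_stats(source, target, direction = names),
    mapping_stats(target, source, direction = rev(names))
  )
}

#' Power-law fit to an alignment-degree histogram
#'
#' Histograms per-entity alignment-partner counts into `n_bins` equal-width
#' bins and fits `log10(frequency) ~ log10(bin center)` by least squares over
#' the non-empty bins. A tight fit (high R-squared) indicates a scale-free
#' alignment graph in which a few hub structures mediate most relationships.
#'
#' @param counts Non-negative per-entity partner counts.
#' @param n_bins Number of equal-width histogram bins (default 100).
#' @return An `fs_powerlaw` list: `exponent` (the slope, negative for a
#'   decaying law), `intercept`, `r_squared`, `bins` (bins used), and the
#'   binned data.
#' @export
degree_powerlaw_fit <- function(counts, n_bins = 100) {
  counts <- counts[is.finite(counts)]
  if (!length(counts)) stopf("no counts supplied")
  breaks <- seq(min(counts), max(counts), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1]) stopf("degenerate counts: all equal")
  h <- graphics::hist(counts, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0 & h$mids > 0
  if (sum(keep) < 3) stopf("fewer than 3 non-empty bins; decrease n_bins")
  lx <- log10(h$mids[keep])
  ly <- log10(h$counts[keep])
  fit <- stats::lm(ly ~ lx)
  r2 <- if (stats::var(ly) == 0) 1 else suppressWarnings(summary(fit))$r.squared
  structure(
    list(exponent = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         bins = sum(keep),
         data = tibble::tibble(center = h$mids[keep], frequency = h$counts[keep])),
    class = "fs_powerlaw"
  )
}

#' @export
print.fs_powerlaw <- function(x, ...) {
  cat(sprintf("<fs_powerlaw> slope %.3f, R^2 = %.3f over %d bins\n",
              x$exponent, x$r_squared, x$bins))
  invisible(x)
}
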
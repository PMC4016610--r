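# internal helpers shared across modules

round_half_up <- function(x) floor(x + 0.5)

# derive an independent sub-seed (< 2^31) from a master seed and a stream name,
# so hierarchy / noise / mask randomness can be varied independently
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009L + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("%s must be a square matrix", what)
  }
  invisible(m)
}

# unordered-pair index helpers: upper triangle, row-major over i < j
upper_pairs <- function(n) which(upper.tri(matrix(0, n, n)))
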
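# Independent oracles and generators shared across test files.

# Per-basepair bitmap oracle over [0, n): element i is TRUE iff 0-based
# position i - 1 is in the set. Set operations on bitmaps are elementwise
# logical operations, independent of the interval code under test.
iv_bitmap <- function(x, n = 1000) {
  b <- logical(n)
  for (i in seq_len(nrow(x))) {
    s <- x$start[i]
    e <- min(x$end[i], n)
    if (s < n && e > s) b[(s + 1):e] <- TRUE
  }
  b
}

iv_from_bitmap <- function(b, chrom = "chr5") {
  if (!any(b)) return(interval_set(chrom = chrom))
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interval_set(starts[r$values] - 1, ends[r$values], chrom = chrom)
}

random_iv <- function(max_coord = 1000, max_n = 5) {
  n <- sample(0:max_n, 1)
  if (n == 0) return(interval_set())
  s <- sample(0:(max_coord - 1), n, replace = TRUE)
  w <- sample(1:150, n, replace = TRUE)
  interval_set(s, pmin(s + w, max_coord))
}

# Small fast screen configuration for repeated simulation tests.
quick_config <- function(seed, n_f2 = 100, ...) {
  sim_config(seed = seed, n_f2 = n_f2,
             true_mutation_pos = sample.int(60.9e6 - 2e6, 1) + 1e6, ...)
}

rw_initial_region <- function() interval_from_1based(1, 60.9e6)

# absolute-band assertion for stochastic estimates ("target +/- tol")
expect_within <- function(x, target, tol) {
  testthat::expect_lte(abs(x - target), tol)
}
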
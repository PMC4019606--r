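# Shared generators for randomized property tests. Every caller sets its own
# seed, so helpers stay pure given the RNG state.

# integer shape quadruples (a1, b1, a2, b2), each in [1, per_max]
random_quadruples <- function(n, per_max = 25L) {
  matrix(sample.int(per_max, 4L * n, replace = TRUE), ncol = 4,
         dimnames = list(NULL, c("a1", "b1", "a2", "b2")))
}

# random count tables with per-sample depth up to max_depth
random_count_pairs <- function(n, max_depth = 30L) {
  d1 <- sample.int(max_depth, n, replace = TRUE)
  d2 <- sample.int(max_depth, n, replace = TRUE)
  nc1 <- vapply(d1, function(d) sample.int(d + 1L, 1L) - 1L, integer(1))
  nc2 <- vapply(d2, function(d) sample.int(d + 1L, 1L) - 1L, integer(1))
  data.frame(nc1 = nc1, c1 = d1 - nc1, nc2 = nc2, c2 = d2 - nc2)
}

# independent hypergeometric upper tail by direct enumeration with choose();
# margins from the 2x2 table (rows = samples, cols = non-converted/converted)
enum_fisher_upper <- function(nc1, c1, nc2, c2) {
  m <- nc1 + nc2   # non-converted total
  n <- c1 + c2     # converted total
  k <- nc1 + c1    # sample 1 depth
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  sum(probs[support >= nc1])
}

# random probability track with n covered positions and gaps >= min_gap
random_track <- function(n, chrom = "chrT", min_gap = 5L, max_gap = 50L) {
  gaps <- sample(min_gap:max_gap, n, replace = TRUE)
  position_track(chrom, cumsum(gaps), runif(n))
}
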
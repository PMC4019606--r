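# The two comparator methods: one-tailed Fisher's exact test on the 2x2
# read-count table, and a one-tailed Z test on Gaussians moment-matched to
# the Beta posteriors. Both are directional with the same convention as the
# exact method: the alternative is "sample 1 more methylated" (p1 > p2).

#' One-tailed Fisher's exact test on the read-count table
#'
#' Builds the 2x2 contingency table (rows = samples, columns =
#' non-converted / converted reads) and returns the hypergeometric
#' upper-tail probability of observing at least the observed `nc1` cell with
#' all margins fixed -- i.e. the one-tailed p-value against the alternative
#' that sample 1 is enriched for non-converted (methylated) reads.
#'
#' Fisher's test breaks down when a row or column sum is zero: the table
#' carries no information about a difference. Such degenerate tables are
#' flagged and given `p_value = 1` rather than raising an error, so
#' simulations can score every site.
#'
#' @inheritParams diff_methylation
#' @return Data frame with columns `p_value` and logical `degenerate`, one
#'   row per table.
#' @examples
#' fisher_one_tailed(3, 1, 1, 3)   # 17/70
#' fisher_one_tailed(0, 5, 0, 5)   # degenerate: no non-converted reads at all
#' @export
fisher_one_tailed <- function(nc1, c1, nc2, c2) {
  .check_counts(nc1, c1, "sample 1 counts")
  .check_counts(nc2, c2, "sample 2 counts")
  n <- max(length(nc1), length(c1), length(nc2), length(c2))
  nc1 <- rep_len(nc1, n); c1 <- rep_len(c1, n)
  nc2 <- rep_len(nc2, n); c2 <- rep_len(c2, n)
  degenerate <- (nc1 + c1) == 0 | (nc2 + c2) == 0 |
    (nc1 + nc2) == 0 | (c1 + c2) == 0
  # P(X >= nc1) drawing n1 = nc1 + c1 reads from nc1 + nc2 non-converted
  # among the grand total, margins fixed
  p <- phyper(nc1 - 1, m = nc1 + nc2, n = c1 + c2, k = nc1 + c1,
              lower.tail = FALSE)
  p[degenerate] <- 1
  data.frame(p_value = pmin(p, 1), degenerate = degenerate)
}

#' One-tailed Z test on moment-matched Gaussians
#'
#' Models each sample's methylation level with a Gaussian carrying the mean
#' and variance of its Beta posterior ([posterior_moments()]), and tests the
#' one-tailed alternative `p1 > p2`:
#' `z = (mean1 - mean2) / sqrt(var1 + var2)`, `p = 1 - Phi(z)`.
#'
#' Beta-posterior variances are strictly positive, so `z` is always finite;
#' identical counts give `z = 0` and `p = 0.5`.
#'
#' @inheritParams diff_methylation
#' @return Numeric vector of one-tailed p-values.
#' @examples
#' z_score_test(3, 1, 1, 3)
#' z_score_test(5, 5, 5, 5)  # 0.5
#' @export
z_score_test <- function(nc1, c1, nc2, c2, prior = c(1, 1)) {
  p1 <- posterior_from_counts(nc1, c1, prior)
  p2 <- posterior_from_counts(nc2, c2, prior)
  m1 <- posterior_moments(p1$alpha, p1$beta)
  m2 <- posterior_moments(p2$alpha, p2$beta)
  z <- (m1$mean - m2$mean) / sqrt(m1$variance + m2$variance)
  pnorm(z, lower.tail = FALSE)
}
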
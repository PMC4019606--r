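# Count-level layer: Beta posteriors from bisulfite read counts and the
# exact differential-methylation probability P(p1 > p2).

.check_counts <- function(nc, c, what = "counts") {
  bad <- !is.finite(nc) | !is.finite(c) | nc < 0 | c < 0 |
    nc != round(nc) | c != round(c)
  if (any(bad)) {
    stop(what, " must be non-negative integers", call. = FALSE)
  }
}

#' Beta posterior of a methylation level from read counts
#'
#' With `k` non-converted (methylated) reads out of `k + c` total, a
#' Beta(prior) prior on the methylation level yields a
#' Beta(k + prior\[1\], c + prior\[2\]) posterior. The default prior is the
#' uniform Beta(1, 1), so zero-depth positions simply return the prior.
#'
#' @param non_converted Non-negative integer vector: reads supporting
#'   methylation.
#' @param converted Non-negative integer vector: reads supporting
#'   non-methylation.
#' @param prior Length-2 positive numeric, pseudo-counts of the Beta prior.
#' @return List with integer-valued numeric vectors `alpha` and `beta`.
#' @examples
#' posterior_from_counts(3, 1) # Beta(4, 2)
#' posterior_from_counts(0, 0) # Beta(1, 1): no data, uniform prior
#' @export
posterior_from_counts <- function(non_converted, converted, prior = c(1, 1)) {
  .check_counts(non_converted, converted, "read counts")
  if (length(prior) != 2 || any(prior <= 0)) {
    stop("prior must be two positive pseudo-counts", call. = FALSE)
  }
  list(alpha = non_converted + prior[1], beta = converted + prior[2])
}

#' Mean and variance of a Beta distribution
#'
#' Closed-form moments: mean `a / (a + b)` and variance
#' `a b / ((a + b)^2 (a + b + 1))`. These are the moments matched by the
#' Gaussian approximation in [z_score_test()] and the variances used by
#' [filter_by_variance()].
#'
#' @param alpha,beta Positive numeric vectors of shape parameters.
#' @return List with numeric vectors `mean` and `variance`.
#' @examples
#' posterior_moments(1, 1)  # mean 0.5, variance 1/12
#' posterior_moments(4, 2)  # mean 2/3, variance 2/63
#' @export
posterior_moments <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("shape parameters must be strictly positive", call. = FALSE)
  }
  s <- alpha + beta
  list(mean = alpha / s, variance = alpha * beta / (s^2 * (s + 1)))
}

#' Exact differential-methylation probability from read counts
#'
#' Converts the two samples' counts into Beta posteriors
#' ([posterior_from_counts()]) and returns the exact
#' `P(p1 > p2)` ([prob_beta_greater()]) together with the posterior means
#' and variances of both samples. This is the quantity printed by the
#' streaming interface: a posterior probability, not a p-value.
#'
#' Zero-depth samples are processed, not rejected -- their posterior is the
#' prior, and the uncertainty shows up in the reported variance.
#'
#' @param nc1,c1 Non-converted and converted read counts of sample 1
#'   (vectors, recycled).
#' @param nc2,c2 Counts of sample 2.
#' @param prior Length-2 Beta prior pseudo-counts (default uniform).
#' @return Data frame with columns `prob_greater`, `mean1`, `var1`,
#'   `mean2`, `var2`, one row per position.
#' @examples
#' diff_methylation(3, 1, 1, 3)   # Beta(4,2) vs Beta(2,4)
#' diff_methylation(0, 0, 0, 0)   # identical priors: prob_greater = 0.5
#' @export
diff_methylation <- function(nc1, c1, nc2, c2, prior = c(1, 1)) {
  p1 <- posterior_from_counts(nc1, c1, prior)
  p2 <- posterior_from_counts(nc2, c2, prior)
  m1 <- posterior_moments(p1$alpha, p1$beta)
  m2 <- posterior_moments(p2$alpha, p2$beta)
  g <- prob_beta_greater(p1$alpha, p1$beta, p2$alpha, p2$beta)
  data.frame(prob_greater = g,
             mean1 = m1$mean, var1 = m1$variance,
             mean2 = m2$mean, var2 = m2$variance)
}

#' Filter positions by posterior uncertainty
#'
#' Keeps the rows whose worse (larger) posterior variance is at most
#' `max_variance`. Filtering on estimated variability rather than raw read
#' depth is the point: the same depth yields different uncertainty depending
#' on how the reads split between non-converted and converted, so a depth
#' cutoff is a poor proxy for certainty.
#'
#' @param results Data frame with columns `var1` and `var2`, e.g. the output
#'   of [diff_methylation()] (extra columns such as positions are carried
#'   through untouched).
#' @param max_variance Maximum tolerated posterior variance, in
#'   `(0, 1/4]`.
#' @return The filtered data frame, original row order preserved.
#' @examples
#' res <- diff_methylation(c(10, 5), c(0, 5), c(0, 0), c(10, 10))
#' filter_by_variance(res, 0.01)
#' @export
filter_by_variance <- function(results, max_variance) {
  if (!all(c("var1", "var2") %in% names(results))) {
    stop("results must contain columns var1 and var2", call. = FALSE)
  }
  if (length(max_variance) != 1 || max_variance <= 0 || max_variance > 0.25) {
    stop("max_variance must lie in (0, 1/4]", call. = FALSE)
  }
  keep <- pmax(results$var1, results$var2) <= max_variance
  results[keep, , drop = FALSE]
}
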
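# Exact computation of g(a1, b1, a2, b2) = P(X > Y) for independent
# X ~ Beta(a1, b1), Y ~ Beta(a2, b2) with positive integer shapes, via a
# linear walk in parameter space driven by single-increment recurrences.
#
# One step changes one shape parameter by +1 and shifts g by a signed
# multiple of the h-term
#
#   h(a1, b1, a2, b2) = B(a1 + a2, b1 + b2) / (B(a1, b1) B(a2, b2)),
#
# always evaluated in log space (Beta-function ratios overflow doubles at
# depths of a few hundred otherwise):
#
#   g(a1 + 1, b1, a2, b2) = g + h / a1
#   g(a1, b1 + 1, a2, b2) = g - h / b1
#   g(a1, b1, a2 + 1, b2) = g - h / a2
#   g(a1, b1, a2, b2 + 1) = g + h / b2
#
# The base case is g(a, b, a, b) = 1/2 (identical continuous distributions),
# used at its cheapest instance (1, 1, 1, 1).

# hard ceiling on a1 + b1 + a2 + b2; the walk is linear in this total and
# anything near it is far beyond realistic WGBS depth
.MAX_TOTAL_ORDER <- 100000L

#' Natural log of the Beta function
#'
#' `ln B(a, b) = lgamma(a) + lgamma(b) - lgamma(a + b)`, finite for all
#' positive arguments. Thin domain-checked wrapper around [base::lbeta()].
#'
#' @param a,b Positive numeric vectors (recycled).
#' @return Numeric vector of `ln B(a, b)`.
#' @examples
#' log_beta_function(1, 1) # 0
#' log_beta_function(2, 2) # log(1/6)
#' @export
log_beta_function <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(a <= 0) || any(b <= 0)) {
    stop("log_beta_function() requires strictly positive arguments", call. = FALSE)
  }
  lbeta(a, b)
}

#' The h-term of the Beta-inequality recursion
#'
#' `h(a1, b1, a2, b2) = B(a1 + a2, b1 + b2) / (B(a1, b1) B(a2, b2))`, the
#' increment applied at each step of the recursive scheme behind
#' [prob_beta_greater()]. Computed as the exponential of a log-Beta
#' combination, so it stays finite at large shape parameters.
#'
#' @param a1,b1 Shape parameters of the first Beta distribution.
#' @param a2,b2 Shape parameters of the second Beta distribution.
#' @return Positive numeric vector; symmetric under swapping the two
#'   parameter pairs.
#' @examples
#' h_term(1, 1, 1, 1) # 1/6
#' @export
h_term <- function(a1, b1, a2, b2) {
  exp(log_beta_function(a1 + a2, b1 + b2) -
        log_beta_function(a1, b1) - log_beta_function(a2, b2))
}

.check_integer_shapes <- function(a1, b1, a2, b2) {
  v <- c(a1, b1, a2, b2)
  if (any(!is.finite(v)) || any(v < 1) || any(v != round(v))) {
    stop("prob_beta_greater() requires integer shape parameters >= 1; ",
         "use prob_beta_greater_quadrature() for real-valued shapes",
         call. = FALSE)
  }
}

# One leg of the walk: raise `dim` from 1 to `target` with the other three
# parameters frozen at `cur`, accumulating all increments in one vectorised
# sum. Divisor at each step is the current value of the raised parameter.
.walk_leg <- function(g, dim, target, cur) {
  if (target == 1L) return(g)
  v <- seq_len(target - 1L)
  p <- list(a1 = cur[["a1"]], b1 = cur[["b1"]], a2 = cur[["a2"]], b2 = cur[["b2"]])
  p[[dim]] <- v
  h <- exp(lbeta(p$a1 + p$a2, p$b1 + p$b2) - lbeta(p$a1, p$b1) - lbeta(p$a2, p$b2))
  sgn <- c(a1 = 1, b1 = -1, a2 = -1, b2 = 1)[[dim]]
  g + sgn * sum(h / v)
}

.prob_beta_greater_one <- function(a1, b1, a2, b2,
                                   order = c("a1", "b1", "a2", "b2")) {
  g <- 0.5
  cur <- c(a1 = 1L, b1 = 1L, a2 = 1L, b2 = 1L)
  tgt <- c(a1 = unname(a1), b1 = unname(b1), a2 = unname(a2), b2 = unname(b2))
  for (dim in order) {
    g <- .walk_leg(g, dim, tgt[[dim]], cur)
    cur[[dim]] <- tgt[[dim]]
  }
  # rounding in the accumulated sum can leave g a hair outside [0, 1]
  min(max(g, 0), 1)
}

#' Exact probability that one Beta variable exceeds another
#'
#' Computes `g = P(X > Y)` for independent `X ~ Beta(a1, b1)` and
#' `Y ~ Beta(a2, b2)` with positive integer shape parameters, exactly up to
#' floating-point rounding. Cost is linear in `a1 + b1 + a2 + b2` and memory
#' is constant: the implementation walks from the identical-distribution base
#' case `g(1, 1, 1, 1) = 1/2` to the target parameters, applying one
#' single-increment recurrence per step with the h-term ([h_term()])
#' evaluated in log space.
#'
#' Count-derived posteriors always have integer shapes; for real-valued
#' shapes use [prob_beta_greater_quadrature()].
#'
#' @param a1,b1 Integer shape parameters (>= 1) of the first Beta.
#' @param a2,b2 Integer shape parameters (>= 1) of the second Beta.
#' @return Numeric vector of probabilities in `[0, 1]` (inputs are recycled
#'   to a common length).
#' @examples
#' prob_beta_greater(1, 1, 1, 1) # 0.5, identical distributions
#' prob_beta_greater(2, 1, 1, 1) # 2/3
#' prob_beta_greater(4, 2, 2, 4) + prob_beta_greater(2, 4, 4, 2) # 1
#' @seealso [prob_beta_greater_quadrature()], [prob_beta_greater_montecarlo()],
#'   [diff_methylation()]
#' @export
prob_beta_greater <- function(a1, b1, a2, b2) {
  .check_integer_shapes(a1, b1, a2, b2)
  n <- max(length(a1), length(b1), length(a2), length(b2))
  a1 <- rep_len(as.integer(a1), n); b1 <- rep_len(as.integer(b1), n)
  a2 <- rep_len(as.integer(a2), n); b2 <- rep_len(as.integer(b2), n)
  tot <- a1 + b1 + a2 + b2
  if (any(tot > .MAX_TOTAL_ORDER)) {
    stop("total order a1 + b1 + a2 + b2 exceeds ", .MAX_TOTAL_ORDER,
         "; refusing the linear walk", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    .prob_beta_greater_one(a1[i], b1[i], a2[i], b2[i])
  }, numeric(1))
}

#' Quadrature oracle for P(X > Y) between Beta distributions
#'
#' Evaluates the defining integral
#' `P(X > Y) = \int_0^1 f_X(x) F_Y(x) dx`, where `f_X` is the Beta(a1, b1)
#' density and `F_Y` the Beta(a2, b2) distribution function (regularised
#' incomplete Beta), by adaptive quadrature. Accepts any positive real
#' shapes and serves as the independent check on the exact recursive engine.
#'
#' @inheritParams prob_beta_greater
#' @param tol Requested absolute accuracy of the integral (default `1e-10`).
#' @return Scalar probability.
#' @examples
#' prob_beta_greater_quadrature(1, 1, 1, 2) # 2/3
#' @export
prob_beta_greater_quadrature <- function(a1, b1, a2, b2, tol = 1e-10) {
  if (any(c(a1, b1, a2, b2) <= 0)) {
    stop("shape parameters must be strictly positive", call. = FALSE)
  }
  res <- integrate(function(x) dbeta(x, a1, b1) * pbeta(x, a2, b2),
                   lower = 0, upper = 1,
                   rel.tol = tol, abs.tol = tol, subdivisions = 500L)
  if (res$message != "OK" || res$abs.error > sqrt(tol)) {
    stop("quadrature did not reach the requested tolerance (",
         res$message, ", abs.error = ", format(res$abs.error), ")",
         call. = FALSE)
  }
  min(max(res$value, 0), 1)
}

#' Monte Carlo oracle for P(X > Y) between Beta distributions
#'
#' Estimates `P(X > Y)` as the fraction of paired draws with `x > y`. A
#' second, fully independent test oracle for [prob_beta_greater()]; also the
#' only route that quantifies its own uncertainty.
#'
#' The caller's RNG state is saved and restored, so the fixed `seed` does
#' not perturb surrounding simulations.
#'
#' @inheritParams prob_beta_greater
#' @param n_samples Number of paired draws (>= 100).
#' @param seed Integer seed; the estimate is bit-reproducible for a fixed seed.
#' @return List with `estimate` and `std_error`
#'   (`sqrt(est * (1 - est) / n_samples)`).
#' @examples
#' prob_beta_greater_montecarlo(2, 1, 1, 1, n_samples = 1e5, seed = 7)
#' @export
prob_beta_greater_montecarlo <- function(a1, b1, a2, b2, n_samples, seed) {
  if (n_samples < 100) stop("n_samples must be at least 100", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x <- rbeta(n_samples, a1, b1)
  y <- rbeta(n_samples, a2, b2)
  est <- mean(x > y)
  list(estimate = est, std_error = sqrt(est * (1 - est) / n_samples))
}
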
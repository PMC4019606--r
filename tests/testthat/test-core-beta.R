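# Exact engine for P(X > Y) between Beta distributions, checked against
# hand-integrable closed forms and two independent oracles.

test_that("log Beta function matches closed-form factorial values", {
  expect_equal(log_beta_function(1, 1), 0)
  expect_equal(log_beta_function(2, 2), log(1 / 6))
  expect_equal(log_beta_function(5, 3), log(1 / 105))
  expect_error(log_beta_function(0, 1), "positive")
  expect_error(log_beta_function(2, -3), "positive")
})

test_that("h-term matches factorial arithmetic and is pair-symmetric", {
  expect_equal(h_term(1, 1, 1, 1), 1 / 6)
  # B(3,2)/(B(2,1) B(1,1)) = (1/12) / (1/2)
  expect_equal(h_term(2, 1, 1, 1), 1 / 6)
  set.seed(101)
  q <- random_quadruples(50, per_max = 30L)
  expect_equal(h_term(q[, 1], q[, 2], q[, 3], q[, 4]),
               h_term(q[, 3], q[, 4], q[, 1], q[, 2]))
  expect_true(all(h_term(q[, 1], q[, 2], q[, 3], q[, 4]) > 0))
})

test_that("identical distributions give exactly one half", {
  expect_identical(prob_beta_greater(1, 1, 1, 1), 0.5)
  expect_equal(prob_beta_greater(7, 3, 7, 3), 0.5, tolerance = 1e-12)
})

test_that("hand-integrable cases agree with the recursion", {
  # P(X > U) for X ~ Beta(2,1): int 2x * x dx = 2/3
  expect_equal(prob_beta_greater(2, 1, 1, 1), 2 / 3, tolerance = 1e-12)
  # Y ~ Beta(1,2): int (1 - (1-x)^2) dx = 2/3
  expect_equal(prob_beta_greater(1, 1, 1, 2), 2 / 3, tolerance = 1e-12)
  expect_equal(prob_beta_greater_quadrature(1, 1, 1, 2), 2 / 3,
               tolerance = 1e-9)
  expect_equal(prob_beta_greater_quadrature(1, 1, 1, 1), 0.5,
               tolerance = 1e-9)
})

test_that("recursion agrees with the quadrature oracle on random shapes", {
  set.seed(202)
  q <- random_quadruples(60, per_max = 25L)
  g <- prob_beta_greater(q[, 1], q[, 2], q[, 3], q[, 4])
  quad <- vapply(seq_len(nrow(q)), function(i) {
    prob_beta_greater_quadrature(q[i, 1], q[i, 2], q[i, 3], q[i, 4])
  }, numeric(1))
  expect_true(all(abs(g - quad) <= 1e-8))
})

test_that("recursion agrees with the Monte Carlo oracle", {
  mc <- prob_beta_greater_montecarlo(2, 1, 1, 1, n_samples = 1e5, seed = 7)
  expect_lt(abs(mc$estimate - 2 / 3), 4 * mc$std_error)
  set.seed(303)
  q <- random_quadruples(10, per_max = 25L)
  for (i in seq_len(nrow(q))) {
    g <- prob_beta_greater(q[i, 1], q[i, 2], q[i, 3], q[i, 4])
    mc <- prob_beta_greater_montecarlo(q[i, 1], q[i, 2], q[i, 3], q[i, 4],
                                       n_samples = 1e5, seed = 400 + i)
    # rule-of-three floor: a saturated estimate (0 discordant draws) has
    # zero plug-in SE but is still consistent with rates up to ~3/n
    tol <- max(4 * mc$std_error, 3 / 1e5)
    expect_lt(abs(g - mc$estimate), tol)
  }
})

test_that("Monte Carlo oracle is bit-reproducible and RNG-clean", {
  a <- prob_beta_greater_montecarlo(4, 2, 2, 4, 1e4, seed = 9)
  b <- prob_beta_greater_montecarlo(4, 2, 2, 4, 1e4, seed = 9)
  expect_identical(a, b)
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(prob_beta_greater_montecarlo(2, 2, 2, 2, 1e3, 5))
  expect_identical(rnorm(3), before)
  expect_error(prob_beta_greater_montecarlo(1, 1, 1, 1, 50, 1), "100")
})

test_that("swap and reflection symmetries hold to near machine precision", {
  set.seed(404)
  q <- random_quadruples(200, per_max = 100L)  # total order up to 400
  g <- prob_beta_greater(q[, 1], q[, 2], q[, 3], q[, 4])
  g_swap <- prob_beta_greater(q[, 3], q[, 4], q[, 1], q[, 2])
  g_refl <- prob_beta_greater(q[, 4], q[, 3], q[, 2], q[, 1])
  expect_true(all(abs(g + g_swap - 1) <= 1e-12))
  expect_true(all(abs(g - g_refl) <= 1e-12))
})

test_that("g is strictly monotone in each shape parameter", {
  set.seed(505)
  q <- random_quadruples(25, per_max = 50L)
  g <- prob_beta_greater(q[, 1], q[, 2], q[, 3], q[, 4])
  expect_true(all(prob_beta_greater(q[, 1] + 1L, q[, 2], q[, 3], q[, 4]) > g))
  expect_true(all(prob_beta_greater(q[, 1], q[, 2] + 1L, q[, 3], q[, 4]) < g))
  expect_true(all(prob_beta_greater(q[, 1], q[, 2], q[, 3] + 1L, q[, 4]) < g))
  expect_true(all(prob_beta_greater(q[, 1], q[, 2], q[, 3], q[, 4] + 1L) > g))
})

test_that("the walk is independent of the parameter-raising order", {
  set.seed(606)
  q <- random_quadruples(30, per_max = 60L)
  orders <- list(c("a1", "b1", "a2", "b2"),
                 c("b2", "a2", "b1", "a1"),
                 c("a1", "a2", "b1", "b2"),
                 c("b1", "b2", "a1", "a2"))
  for (i in seq_len(nrow(q))) {
    vals <- vapply(orders, function(ord) {
      betadiff:::.prob_beta_greater_one(q[i, 1], q[i, 2], q[i, 3], q[i, 4],
                                        order = ord)
    }, numeric(1))
    expect_lt(max(vals) - min(vals), 1e-10)
  }
})

test_that("output stays in [0, 1] at high total order", {
  g <- prob_beta_greater(c(1200L, 10L, 1000L), c(800L, 1990L, 1000L),
                         c(900L, 1990L, 1000L), c(1100L, 10L, 1000L))
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(g[3], 0.5, tolerance = 1e-10)
})

test_that("invalid shapes are rejected with actionable errors", {
  expect_error(prob_beta_greater(1.5, 1, 1, 1), "quadrature")
  expect_error(prob_beta_greater(0, 1, 1, 1), "integer")
  expect_error(prob_beta_greater(60000, 60000, 1, 1), "total order")
  expect_error(prob_beta_greater_quadrature(-1, 1, 1, 1), "positive")
})
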
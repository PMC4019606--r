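# Binomial site simulation, unified evidence scores, ROC construction and
# the three-method benchmark.

test_that("simulated counts are reproducible binomials with full depth", {
  a <- simulate_site_pairs(0.5, 0.5, 20, 20, n_sites = 5000, seed = 1)
  b <- simulate_site_pairs(0.5, 0.5, 20, 20, n_sites = 5000, seed = 1)
  expect_identical(a, b)
  expect_true(all(a$nc1 + a$c1 == 20))
  expect_true(all(a$nc2 + a$c2 == 20))
  # binomial mean check: SE of the mean of 5000 Binomial(20, 0.5) draws
  se <- sqrt(20 * 0.25 / 5000)
  expect_lt(abs(mean(a$nc1) - 10), 4 * se)
  expect_error(simulate_site_pairs(0, 0.5, 10, 10, 10, 1), "inside")
  expect_error(simulate_site_pairs(0.5, 0.5, 0, 10, 10, 1), ">= 1")
})

test_that("simulation restores the caller's RNG state", {
  set.seed(2); before <- rnorm(3)
  set.seed(2); invisible(simulate_site_pairs(0.3, 0.7, 5, 5, 100, seed = 9))
  expect_identical(rnorm(3), before)
})

test_that("evidence scores are minimal for identical counts, maximal for opposites", {
  same <- data.frame(nc1 = 5, c1 = 5, nc2 = 5, c2 = 5)
  opposite <- data.frame(nc1 = 20, c1 = 0, nc2 = 0, c2 = 20)
  for (m in c("beta_exact", "fisher", "z_score")) {
    expect_equal(score_sites(same, m), 0)
    expect_gt(score_sites(opposite, m), 0.99)
  }
  expect_error(score_sites(same, "mystery"))
})

test_that("scores stay in [0, 1] and degenerate Fisher tables carry no evidence", {
  set.seed(53)
  s <- random_count_pairs(1000, max_depth = 25L)
  for (m in c("beta_exact", "fisher", "z_score")) {
    sc <- score_sites(s, m)
    expect_true(all(sc >= 0 & sc <= 1))
  }
  deg <- data.frame(nc1 = 0, c1 = 5, nc2 = 0, c2 = 5)
  expect_identical(score_sites(deg, "fisher"), 0)
})

test_that("ROC endpoints and degenerate inputs behave as defined", {
  r <- roc_curve(rep(1, 10), rep(0, 10), thresholds = c(-0.1, 0.5, 1.1))
  expect_equal(r$tpr, c(1, 1, 0))
  expect_equal(r$fpr, c(1, 0, 0))
  # identical score distributions track the chance line
  x <- seq(0, 1, length.out = 100)
  r2 <- roc_curve(x, x, thresholds = seq(0, 1, by = 0.1))
  expect_equal(r2$tpr, r2$fpr)
  expect_error(roc_curve(numeric(0), 1, 0.5), "non-empty")
  expect_error(roc_curve(1, 1, c(0.5, 0.1)), "sorted")
})

test_that("ROC rates tie out against direct counting on random scores", {
  set.seed(59)
  pos <- runif(200); neg <- runif(300)
  thr <- sort(runif(50))
  r <- roc_curve(pos, neg, thr)
  expect_equal(r$tpr, vapply(thr, function(t) mean(pos >= t), numeric(1)))
  expect_equal(r$fpr, vapply(thr, function(t) mean(neg >= t), numeric(1)))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(p1_alt = 0.4, p2_alt = 0.4), "differ")
  expect_error(simulation_config(p_null = 1), "inside")
  expect_error(simulation_config(depth1 = 0), ">= 1")
  expect_error(run_benchmark(list()), "simulation_config")
})

test_that("the benchmark is deterministic and its ROC curves are monotone", {
  cfg <- simulation_config(depth1 = 5, depth2 = 5, n_sites = 300, seed = 11)
  b1 <- run_benchmark(cfg)
  b2 <- run_benchmark(cfg)
  expect_identical(b1, b2)
  for (m in unique(b1$roc$method)) {
    r <- b1$roc[b1$roc$method == m, ]
    expect_true(all(diff(r$tpr) <= 0))  # non-increasing in the threshold
    expect_true(all(diff(r$fpr) <= 0))
    expect_true(all(r$tpr >= 0 & r$tpr <= 1))
  }
  # histograms account for every site in both classes
  counts <- tapply(b1$histograms$count,
                   interaction(b1$histograms$method, b1$histograms$class),
                   sum)
  expect_true(all(counts == cfg$n_sites))
})

test_that("under the null the mean exact probability is one half", {
  b <- run_benchmark(simulation_config(depth1 = 10, depth2 = 10,
                                       n_sites = 2000, seed = 13))
  neg <- simulate_site_pairs(0.5, 0.5, 10, 10, 2000, seed = 13)
  g <- diff_methylation(neg$nc1, neg$c1, neg$nc2, neg$c2)$prob_greater
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - 0.5), 4 * se)
  # and the folded control scores concentrate low for the exact method
  ctrl <- b$scores[b$scores$class == "control", "beta_exact"]
  expect_lt(mean(ctrl), mean(b$scores[b$scores$class == "positive", "beta_exact"]))
})

test_that("method comparison table and 2-D histogram bin consistently", {
  set.seed(61)
  s <- random_count_pairs(400, max_depth = 15L)
  mc <- method_comparison(s)
  expect_named(mc, c("prob_greater", "fisher_p", "fisher_degenerate", "z_p"))
  h <- hist2d(mc$prob_greater, 1 - mc$z_p, nbins = 20)
  expect_equal(sum(h$count), nrow(s))
  expect_true(all(h$count > 0))
  expect_error(hist2d(1:3 / 3, 1:2 / 2), "equal length")
})

test_that("benchmark TSV export round-trips through read.delim", {
  b <- run_benchmark(simulation_config(depth1 = 5, depth2 = 5,
                                       n_sites = 100, seed = 17))
  roc_path <- withr::local_tempfile(fileext = ".tsv")
  hist_path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark_tsv(b, roc_path, hist_path)
  roc_in <- read.delim(roc_path)
  expect_equal(nrow(roc_in), nrow(b$roc))
  expect_equal(roc_in$tpr, b$roc$tpr)
  hist_in <- read.delim(hist_path)
  expect_equal(sum(hist_in$count), sum(b$histograms$count))
})
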
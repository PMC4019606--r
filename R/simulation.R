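# Simulation benchmark: binomial count generation for null and alternative
# site pairs, a unified "evidence of difference" score for the three methods,
# and ROC construction across coverages.

#' Configuration of a benchmark simulation
#'
#' Negative-control sites draw both samples' counts from the same binomial
#' probability `p_null`; true-positive sites use the markedly different
#' probabilities `p1_alt` and `p2_alt`. Defaults are a fifty-percent
#' methylated null against a 0.3 vs 0.7 alternative with 2000 sites per
#' class -- a difference large enough that failures to detect it are
#' attributable to the scoring method, not to the effect size.
#'
#' @param p_null Binomial probability shared by both samples at control
#'   sites, in (0, 1).
#' @param p1_alt,p2_alt Distinct binomial probabilities of the two samples
#'   at true-positive sites.
#' @param depth1,depth2 Reads per sample at every site (>= 1).
#' @param n_sites Sites per class (>= 1).
#' @param seed Master integer seed; the null and alternative count streams
#'   are derived from it deterministically.
#' @return A `simulation_config` list.
#' @examples
#' simulation_config(depth1 = 5, depth2 = 5, seed = 1)
#' @export
simulation_config <- function(p_null = 0.5, p1_alt = 0.3, p2_alt = 0.7,
                              depth1 = 20, depth2 = 20,
                              n_sites = 2000, seed = 1) {
  probs <- c(p_null, p1_alt, p2_alt)
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (p1_alt == p2_alt) {
    stop("p1_alt and p2_alt must differ: identical probabilities are a ",
         "null configuration, not a positive class", call. = FALSE)
  }
  if (depth1 < 1 || depth2 < 1 || n_sites < 1) {
    stop("depths and n_sites must be >= 1", call. = FALSE)
  }
  structure(list(p_null = p_null, p1_alt = p1_alt, p2_alt = p2_alt,
                 depth1 = as.integer(depth1), depth2 = as.integer(depth2),
                 n_sites = as.integer(n_sites), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate paired bisulfite counts at independent sites
#'
#' At each site, sample 1's non-converted count is Binomial(`depth1`, `p1`)
#' and sample 2's is Binomial(`depth2`, `p2`), independently; converted
#' counts make up the remaining depth. The caller's RNG state is restored on
#' exit, so the fixed `seed` fully determines the output without perturbing
#' surrounding code.
#'
#' @param p1,p2 Underlying binomial methylation probabilities in (0, 1).
#' @param depth1,depth2 Reads per sample (>= 1).
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed.
#' @return Data frame with columns `nc1`, `c1`, `nc2`, `c2`.
#' @examples
#' simulate_site_pairs(0.5, 0.5, 20, 20, n_sites = 5, seed = 1)
#' @export
simulate_site_pairs <- function(p1, p2, depth1, depth2, n_sites, seed) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (depth1 < 1 || depth2 < 1 || n_sites < 1) {
    stop("depths and n_sites must be >= 1", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nc1 <- rbinom(n_sites, depth1, p1)
  nc2 <- rbinom(n_sites, depth2, p2)
  data.frame(nc1 = nc1, c1 = depth1 - nc1, nc2 = nc2, c2 = depth2 - nc2)
}

#' Score sites on a common evidence-of-difference scale
#'
#' The three methods output incommensurable quantities (a posterior
#' probability for the exact Beta method, one-tailed p-values for Fisher and
#' Z). To put them on one ROC axis each site is folded to a two-sided
#' "evidence of any difference" score in `[0, 1]`, higher = more evidence,
#' without changing any method's ranking of sites:
#' \itemize{
#'   \item `beta_exact`: `2 * |g - 0.5|` with `g = P(p1 > p2)`;
#'   \item `z_score`: `1 - 2 * min(p, 1 - p)` for the one-tailed p (the
#'     usual two-sided fold of a continuous test);
#'   \item `fisher`: `1 - 2 * min(p_upper, p_lower)` using both one-tailed
#'     hypergeometric tails. For a discrete test `1 - p_upper` understates
#'     the lower tail by the point mass at the observed table, so the lower
#'     tail is computed directly; degenerate tables (a zero row or column)
#'     carry no evidence and score 0.
#' }
#'
#' @param sites Data frame with columns `nc1`, `c1`, `nc2`, `c2`.
#' @param method One of `"beta_exact"`, `"fisher"`, `"z_score"`.
#' @param prior Beta prior pseudo-counts for the Beta and Z methods.
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' s <- data.frame(nc1 = c(5, 20), c1 = c(5, 0), nc2 = c(5, 0), c2 = c(5, 20))
#' score_sites(s, "beta_exact")
#' score_sites(s, "fisher")
#' @export
score_sites <- function(sites, method = c("beta_exact", "fisher", "z_score"),
                        prior = c(1, 1)) {
  method <- match.arg(method)
  if (nrow(sites) == 0) stop("sites must be non-empty", call. = FALSE)
  if (method == "beta_exact") {
    g <- diff_methylation(sites$nc1, sites$c1, sites$nc2, sites$c2,
                          prior = prior)$prob_greater
    return(2 * abs(g - 0.5))
  }
  if (method == "z_score") {
    p <- z_score_test(sites$nc1, sites$c1, sites$nc2, sites$c2, prior = prior)
    return(1 - 2 * pmin(p, 1 - p))
  }
  ft <- fisher_one_tailed(sites$nc1, sites$c1, sites$nc2, sites$c2)
  p_lower <- phyper(sites$nc1, m = sites$nc1 + sites$nc2,
                    n = sites$c1 + sites$c2, k = sites$nc1 + sites$c1)
  score <- pmax(1 - 2 * pmin(ft$p_value, p_lower), 0)
  score[ft$degenerate] <- 0
  score
}

#' ROC curve from positive and negative scores
#'
#' For each threshold `t`, the true-positive rate is the fraction of
#' positive-class scores `>= t` and the false-positive rate the fraction of
#' negative-class scores `>= t`. Both are non-increasing in `t`.
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors.
#' @param thresholds Sorted numeric vector of thresholds.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @examples
#' roc_curve(c(1, 1, 0.9), c(0, 0.1, 0), thresholds = c(0, 0.5, 1))
#' @export
roc_curve <- function(pos_scores, neg_scores, thresholds) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("score vectors must be non-empty", call. = FALSE)
  }
  if (is.unsorted(thresholds)) {
    stop("thresholds must be sorted increasingly", call. = FALSE)
  }
  ps <- sort(pos_scores)
  ns <- sort(neg_scores)
  # fraction >= t via a count of strictly smaller elements
  tpr <- (length(ps) - findInterval(thresholds, ps, left.open = TRUE)) / length(ps)
  fpr <- (length(ns) - findInterval(thresholds, ns, left.open = TRUE)) / length(ns)
  data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
}

.default_threshold_grid <- function(scores) {
  sort(unique(c(seq(0, 1, length.out = 512), scores)))
}

#' Run the three-method benchmark at one coverage configuration
#'
#' Simulates negative-control sites (both samples at `p_null`) and
#' true-positive sites (`p1_alt` vs `p2_alt`) from `config`, scores every
#' site with the exact Beta method, Fisher's test and the Z test
#' ([score_sites()]), and builds one ROC table per method over a shared
#' threshold grid (512 evenly spaced values in `[0, 1]` plus every attained
#' score, so ROC steps are exact). Identical configurations produce
#' identical results bit for bit.
#'
#' @param config A [simulation_config()].
#' @return List of class `benchmark_result` with elements
#'   \describe{
#'     \item{config}{the input configuration}
#'     \item{roc}{data frame `method`, `threshold`, `fpr`, `tpr`}
#'     \item{histograms}{data frame `method`, `class`, `bin_left`,
#'       `bin_right`, `count` -- score distributions in 50 equal bins,
#'       positives and controls separately}
#'     \item{scores}{per-site data frame `class`, `beta_exact`, `fisher`,
#'       `z_score`}
#'   }
#' @examples
#' b <- run_benchmark(simulation_config(depth1 = 5, depth2 = 5,
#'                                      n_sites = 200, seed = 1))
#' head(b$roc)
#' @export
run_benchmark <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be created by simulation_config()", call. = FALSE)
  }
  neg <- simulate_site_pairs(config$p_null, config$p_null,
                             config$depth1, config$depth2,
                             config$n_sites, seed = config$seed)
  pos <- simulate_site_pairs(config$p1_alt, config$p2_alt,
                             config$depth1, config$depth2,
                             config$n_sites, seed = config$seed + 1L)
  methods <- c("beta_exact", "fisher", "z_score")
  sp <- lapply(methods, function(m) score_sites(pos, m))
  sn <- lapply(methods, function(m) score_sites(neg, m))
  names(sp) <- names(sn) <- methods

  grid <- .default_threshold_grid(c(unlist(sp), unlist(sn)))
  roc <- do.call(rbind, lapply(methods, function(m) {
    cbind(method = m, roc_curve(sp[[m]], sn[[m]], grid))
  }))

  breaks <- seq(0, 1, length.out = 51L)
  hist_one <- function(x, m, cl) {
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE),
                       nbins = length(breaks) - 1L)
    data.frame(method = m, class = cl,
               bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
               count = counts)
  }
  histograms <- do.call(rbind, c(
    lapply(methods, function(m) hist_one(sp[[m]], m, "positive")),
    lapply(methods, function(m) hist_one(sn[[m]], m, "control"))))

  scores <- rbind(
    data.frame(class = "positive", beta_exact = sp$beta_exact,
               fisher = sp$fisher, z_score = sp$z_score),
    data.frame(class = "control", beta_exact = sn$beta_exact,
               fisher = sn$fisher, z_score = sn$z_score))

  structure(list(config = config, roc = roc, histograms = histograms,
                 scores = scores),
            class = "benchmark_result")
}

#' Interpolated TPR at a false-positive-rate budget
#'
#' Convenience accessor: the highest TPR achieved by `method` at any
#' threshold whose FPR does not exceed `max_fpr`.
#'
#' @param benchmark A `benchmark_result` from [run_benchmark()].
#' @param method Method label present in the ROC table.
#' @param max_fpr FPR budget in `[0, 1]`.
#' @return Scalar TPR (0 if no threshold meets the budget).
#' @export
tpr_at_fpr <- function(benchmark, method, max_fpr) {
  roc <- benchmark$roc
  sel <- roc$method == method & roc$fpr <= max_fpr
  if (!any(sel)) return(0)
  max(roc$tpr[sel])
}

#' Per-site output of all three methods on a set of count pairs
#'
#' Returns, for each site, the exact posterior probability `P(p1 > p2)` and
#' the one-tailed Fisher and Z p-values -- the raw ingredients of a
#' method-against-method comparison (e.g. a two-dimensional histogram of the
#' Beta probability against either p-value).
#'
#' @param sites Data frame with columns `nc1`, `c1`, `nc2`, `c2`.
#' @param prior Beta prior pseudo-counts.
#' @return Data frame with columns `prob_greater`, `fisher_p`,
#'   `fisher_degenerate`, `z_p`.
#' @examples
#' method_comparison(data.frame(nc1 = 3, c1 = 1, nc2 = 1, c2 = 3))
#' @export
method_comparison <- function(sites, prior = c(1, 1)) {
  g <- diff_methylation(sites$nc1, sites$c1, sites$nc2, sites$c2,
                        prior = prior)$prob_greater
  ft <- fisher_one_tailed(sites$nc1, sites$c1, sites$nc2, sites$c2)
  zp <- z_score_test(sites$nc1, sites$c1, sites$nc2, sites$c2, prior = prior)
  data.frame(prob_greater = g, fisher_p = ft$p_value,
             fisher_degenerate = ft$degenerate, z_p = zp)
}

#' Two-dimensional histogram of two bounded scores
#'
#' Bins paired values on a square grid over `[0, 1] x [0, 1]`; the long
#' output format (one row per non-empty cell) is convenient both for
#' plotting and for TSV export.
#'
#' @param x,y Equal-length numeric vectors in `[0, 1]`.
#' @param nbins Number of bins per axis.
#' @return Data frame with columns `x_left`, `x_right`, `y_left`, `y_right`,
#'   `count`, restricted to non-empty cells.
#' @export
hist2d <- function(x, y, nbins = 50L) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  breaks <- seq(0, 1, length.out = nbins + 1L)
  ix <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- table(ix, iy)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, , drop = FALSE]
  ix <- as.integer(df$ix); iy <- as.integer(df$iy)
  data.frame(x_left = breaks[ix], x_right = breaks[ix + 1L],
             y_left = breaks[iy], y_right = breaks[iy + 1L],
             count = df$Freq)
}

#' Export benchmark ROC curves and score histograms as TSV
#'
#' @param benchmark A `benchmark_result` from [run_benchmark()].
#' @param roc_path,hist_path Output file paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the benchmark object.
#' @export
write_benchmark_tsv <- function(benchmark, roc_path = NULL, hist_path = NULL) {
  if (!is.null(roc_path)) {
    write.table(benchmark$roc, roc_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(hist_path)) {
    write.table(benchmark$histograms, hist_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(benchmark)
}
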
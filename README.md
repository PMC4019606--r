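# betadiff

Exact differential-methylation probabilities from whole-genome bisulfite
sequencing (WGBS) read counts.

At a genomic position, WGBS yields `k` non-converted (methylated) reads out
of `n` for each sample. Under a uniform prior the methylation level of
sample *i* has posterior `p_i ~ Beta(k_i + 1, n_i - k_i + 1)`, and the
natural measure of differential methylation is not a p-value but the
posterior probability

```
g(a1, b1, a2, b2) = P(p1 > p2),   p1 ~ Beta(a1, b1), p2 ~ Beta(a2, b2).
```

`betadiff` computes `g` **exactly** (to floating-point rounding) in time
linear in total read depth, using single-increment recurrences on the Beta
shape parameters with the increment term
`h = B(a1 + a2, b1 + b2) / (B(a1, b1) B(a2, b2))` evaluated in log space,
starting from the base case `g(1, 1, 1, 1) = 1/2`. Two independent oracles
(adaptive quadrature of `∫ f_X F_Y` and Monte Carlo) verify the engine in
the test suite.

Around the core, the package provides:

- the two approximations commonly used instead — a one-tailed Fisher exact
  test on the 2×2 read-count table and a one-tailed Z test on
  moment-matched Gaussians — under one directional convention;
- a simulation benchmark comparing all three methods by ROC curves across
  coverages (at depth 5 per sample, Fisher's accumulated false negatives
  cap its true-positive rate well below the exact method's; at depth 50
  the methods converge);
- per-nucleotide probability tracks for differentially methylated regions:
  Gaussian-kernel smoothing, window averaging, region means, variance-based
  position filtering, bedGraph export and BED3 region input — no hard DMR
  boundaries anywhere;
- a streaming CLI speaking the classic four-integer stdin/stdout protocol.

## Worked example

Sample 1 shows 3 methylated and 1 unmethylated read; sample 2 the reverse.

```r
library(betadiff)

diff_methylation(3, 1, 1, 3)
#>   prob_greater     mean1       var1     mean2       var2
#> 1    0.8968254 0.6666667 0.03174603 0.3333333 0.03174603

fisher_one_tailed(3, 1, 1, 3)
#>     p_value degenerate
#> 1 0.2428571      FALSE

z_score_test(3, 1, 1, 3)
#> [1] 0.09293837
```

The exact posterior says sample 1 is more methylated with probability
0.897 — substantial evidence from 4 reads per sample. Fisher's test at the
same position returns p = 0.243 (= 17/70, the hypergeometric tail):
at this depth the contingency table simply cannot reach conventional
significance, which is how Fisher accumulates false negatives at low
coverage. The Z p-value of 0.093 sits in between.

The same computation streams from the shell, one position per line
(`nc1 c1 nc2 c2`):

```sh
printf '3 1 1 3\n0 0 0 0\n' | \
  Rscript "$(Rscript -e 'cat(system.file("cli","methyl_diff.R",package="betadiff"))')" diff
#> 0.896825
#> 0.5
```

Subcommands `benchmark`, `smooth` and `fixture` expose the ROC comparison,
the track smoother (position file → bedGraph) and the synthetic
position-file generator; each prints its options with `--help`.

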
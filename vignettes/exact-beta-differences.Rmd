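---
title: "Exact Beta inequalities for differential methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Beta inequalities for differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadiff)
```

## The model

Whole-genome bisulfite sequencing reports, at a genomic position, $k$
non-converted reads (supporting methylation) out of $n$ total. If the
fraction $p$ of methylated strands in the cell population were known, $k$
would be Binomial$(n, p)$. With a uniform prior on $p$ the posterior is
Beta$(k + 1,\; n - k + 1)$ — conjugacy with no free hyperparameters. The
prior pseudo-counts are exposed as an option (`prior =`) but default to the
uniform $(1, 1)$ everywhere.

Differential methylation between two samples is then not a hypothesis test
but a posterior probability,
$$
g(a_1, b_1, a_2, b_2) \;=\; P(p_1 > p_2), \qquad
p_i \sim \mathrm{Beta}(a_i, b_i)\ \text{independently},
$$
with $a_i = k_i + 1$, $b_i = n_i - k_i + 1$. A value of $g$ near $1$ means
sample 1 is almost surely more methylated, near $0$ the reverse, and $0.5$
means the data are uninformative about the direction. The package fixes the
reported direction as $P(p_1 > p_2)$; the complement is always available by
swapping the samples, and `diff_methylation()` is tested to respect
$g + g^{\mathrm{swap}} = 1$ exactly.

## The exact engine

By definition $g = \int_0^1 f_{X}(x)\, F_{Y}(x)\, dx$ with $f_X$ the first
Beta density and $F_Y$ the second's CDF (the regularised incomplete Beta).
For integer shapes — the only shapes count data produce — $g$ obeys
single-increment recurrences built on the quantity
$$
h(a_1, b_1, a_2, b_2) = \frac{B(a_1 + a_2,\, b_1 + b_2)}
                              {B(a_1, b_1)\, B(a_2, b_2)} ,
$$
one per parameter: raising $a_1$ adds $h/a_1$, raising $b_2$ adds $h/b_2$,
raising $b_1$ or $a_2$ subtracts $h/b_1$ or $h/a_2$. Since identically
distributed continuous variables satisfy $P(X > Y) = 1/2$, the cheapest
base case is $g(1,1,1,1) = 1/2$, and any integer target is reached by a
walk of $a_1 + b_1 + a_2 + b_2 - 4$ increments.

Implementation choices:

* **Iterative walk, fixed leg order.** The recursion is realised as a loop,
  raising $a_1$ fully, then $b_1$, then $a_2$, then $b_2$ — $O(\text{total
  order})$ time, $O(1)$ memory, no recursion depth to exhaust. The result is
  mathematically independent of the leg order; a property test compares four
  different orders and requires agreement to $10^{-10}$, while fixing one
  default order keeps the output bit-deterministic.
* **All $h$ evaluations in log space.** $B(a,b)$ underflows and its ratios
  overflow doubles at read depths of a few hundred; `lbeta()` combinations
  exponentiated per step keep every intermediate finite. The engine is
  exercised in tests at total order 4000 and stays in $[0, 1]$.
* **Integer shapes only.** The increment recurrences cannot reach the
  integer base case from non-integer starts, so the exact engine rejects
  them with a pointer to the quadrature routine, which accepts any positive
  reals.
* **A guard at total order $10^5$.** The walk is linear in depth; the guard
  sits far above any realistic WGBS coverage and exists to fail loudly on
  nonsense input rather than loop for minutes.
* **Clamping.** The accumulated sum can land a few ulp outside $[0, 1]$;
  the result is clamped. Tests assert symmetry identities to $10^{-12}$,
  comfortably inside what ~400-term sums of exactly-computed increments
  leave as rounding residue.

Two independent oracles check the engine: adaptive quadrature of the
defining integral (`stats::integrate`, absolute tolerance $10^{-10}$,
chosen to out-precision the $10^{-8}$ agreement the tests demand) and plain
Monte Carlo with $10^5$ paired draws. Monte Carlo comparisons use four
plug-in standard errors with a *rule-of-three* floor: when all $10^5$ draws
agree, the plug-in SE is zero, yet the estimate is still consistent with
discordance rates up to about $3/n$ — without the floor a saturated
estimate would spuriously reject an engine value of, say, $0.99996$.

## The two approximations

Both comparators are one-tailed with the same direction as $g$
("sample 1 more methylated"), so all three methods rank sites on one axis.

**Fisher's exact test** acts on the 2×2 table of non-converted/converted
counts by sample. The one-tailed p-value is the hypergeometric upper tail
$P(\text{cell} \ge nc_1)$ with margins fixed, computed by `stats::phyper`
and cross-checked in tests against an independent `choose()`-based
enumeration and `stats::fisher.test(alternative = "greater")`. Tables with
a zero row or column carry no information about a difference; they are
flagged degenerate and given $p = 1$ rather than an error, so simulations
can score every site. No mid-p correction is applied: the plain tail is
what the comparison is about.

**The Z test** replaces each Beta posterior with a Gaussian of the same
mean $a/(a+b)$ and variance $ab/\big((a+b)^2(a+b+1)\big)$ and reports
$1 - \Phi(z)$ for $z = (\mu_1 - \mu_2)/\sqrt{v_1 + v_2}$. Matching the
*posterior* moments (counts + 1), not raw proportions, keeps the Z test on
the same Bayesian footing and makes it well-defined at zero depth. At depth
1000 the tests require $|(1 - p_Z) - g| \le 0.01$ across random count
pairs — the central-limit regime where the two methods coincide.

## The benchmark

`run_benchmark()` reproduces the simulation design: negative-control sites
draw both samples' counts from one binomial probability; true positives
use markedly different probabilities. The configuration defaults are
$p_{\text{null}} = 0.5$, alternatives $0.3$ vs $0.7$, 2000 sites per class,
with coverage the axis of interest (the tests exercise depths 5 and 50; the
interesting grid is roughly 5–50). These numbers are the package's fixed
study conditions: a half-methylated background is the hardest null (maximal
binomial variance), and a 0.4 swing is a difference any method *should*
find given enough reads, so failures at low depth isolate the scoring
method rather than the effect size.

To place a posterior probability and two one-tailed p-values on one ROC
axis, every site is folded to a two-sided "evidence of any difference"
score in $[0, 1]$:

* exact method: $2\,|g - 0.5|$;
* Z test: $1 - 2\min(p, 1 - p)$, the usual fold of a continuous one-tailed
  p-value;
* Fisher: $1 - 2\min(p_{\text{upper}}, p_{\text{lower}})$ with *both*
  hypergeometric tails computed directly. For a discrete test
  $1 - p_{\text{upper}}$ is $P(\text{cell} < nc_1)$, which understates the
  lower tail by the point mass at the observed table; folding with the true
  lower tail avoids labelling uninformative boundary tables (e.g.
  $nc_1 = 0$ with ordinary margins, where $p_{\text{upper}} = 1$) as
  maximal evidence. Degenerate tables score $0$: an uninformative test
  cannot call a difference, which is precisely how low coverage turns into
  false negatives for Fisher.

Each fold is monotone in its method's own output on either side of the
null, so method-internal site rankings are preserved. The threshold grid is
512 evenly spaced values plus every attained score, making the ROC steps
exact without quadratic blowup; `tpr_at_fpr()` reads off the TPR at a
false-positive budget.

At depth 5 per sample the folded Fisher scores take only a handful of
values, and a large fraction of genuinely different sites produce
unremarkable tables: Fisher's TPR plateaus near 0.75 in the packaged
configuration while the exact method passes 0.98 — the approximation's
false negatives are structural, not a threshold choice. At depth 50 all
three methods exceed 0.9 TPR at a 5% FPR budget and the choice stops
mattering.

### What the generator does and does not emulate

Simulated sites are independent, share one depth per sample, and draw from
exact binomials. Real WGBS data have spatially correlated methylation,
position-dependent coverage, incomplete bisulfite conversion,
strand/context structure and mapping artefacts — none of which are
modelled. Passing benchmarks therefore demonstrates the statistical
ordering of the three scoring rules under clean binomial sampling, not
end-to-end performance on real libraries; the track layer below exists
precisely because real data need spatial treatment that per-site
simulation cannot exercise.

## Probability tracks instead of DMR boundaries

Calling discrete differentially methylated regions forces ad hoc rules —
minimum length, maximum gap, intersection conventions. The track layer
avoids them: every covered position keeps its probability, and analysis
happens on the track.

* `smooth_track()` is a Nadaraya–Watson average with a Gaussian kernel over
  genomic distance, evaluated at the covered positions, weights truncated
  beyond four bandwidths (a weight below $e^{-8} \approx 3\times10^{-4}$ of
  the self-weight; the truncation bounds the cost and makes "bandwidth far
  below the inter-position gap" an exact identity). The kernel is the
  standard default; the bandwidth is deliberately a user choice, since the
  right smoothing scale for methylation is usually unknown a priori.
  Uncovered bases are not imputed — only covered positions carry weight.
* `window_average()` clumps runs of covered positions into block means; the
  trailing partial block averages over its own size, so block means times
  block sizes conserve the value total exactly (tested to $10^{-12}$).
* `region_mean()` reports per-region means of covered positions with `NA`
  as an explicit no-data marker, supporting "annotated regions vs
  comparison regions" questions. Sampling of background regions is left to
  the caller, who knows the genome's annotation structure.

Coordinate conventions: tracks are 1-based positions (matching position
files); regions are `GRanges`, the 1-based closed Bioconductor convention,
because BED input and bedGraph output flow through `rtracklayer`, which
performs the 0-based half-open conversions at the file boundary. One
container with well-tested conversions beats a private interval type.

## The stream interface

`stream_diff()` implements the four-integer stdin/stdout protocol: one
line in, one probability out, order preserved, single pass, constant
memory. Output is formatted at six significant digits by default — a fixed
format makes the stream deterministic and diffable; the full-precision
values are always available through the R API. `--fields` (or the `fields`
argument) maps counts embedded in wider tables instead of guessing column
positions. The fixture writer generates a synthetic position file with a
differentially methylated middle third flanked by null sites, exercising
the stream, the track layer and the smoother together.

## Problem sizes and runtime

The test suite runs 200-quadruple oracle sweeps (shapes ≤ 25), 500-quadruple
symmetry sweeps (total order ≤ 400), benchmarks of 2000 sites per class at
depths 5 and 50, a $10^4$-site null calibration and $10^4$-position track
checks; the full suite completes in well under a minute on one core. These
sizes were chosen so that every Monte Carlo band in the tests is at least
four standard errors wide at the simulated scale.

## Known limitations

* The exact engine requires integer shapes; informative non-integer priors
  route through quadrature only.
* No spatial model: smoothing bandwidth is a user choice, and correlation
  length is not estimated from data.
* No strand merging, context calling, or conversion-efficiency correction;
  inputs are assumed to be already-tallied counts.
* `P(p_1 > p_2 + \delta)` offsets and credible intervals on $p_1 - p_2$
  are out of scope; the output is the single inequality probability.
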
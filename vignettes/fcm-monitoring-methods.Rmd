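---
title: "Methods: simulating and evaluating preharvest FCM infestation monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating preharvest FCM infestation monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmonitor)
```

## The measurement problem

False codling moth (FCM, *Thaumatotibia leucotreta*) larvae infest citrus
fruit, and every infested fruit abscises and falls within a few weeks of
infestation. Collecting *all* fallen fruit from an orchard floor therefore
yields an absolute weekly measurement of the infestation process, not a
sample. The monitoring metric is

> infestation rate = infested fallen fruit in the past 7 days / total
> trees in the orchard  (infested fruit per tree per week),

with an action threshold of 0.1. Exceedance is *strict* (`rate > 0.1`):
the protocol reacts to *more than* 0.1 infested fruit per tree per week,
so a rate landing exactly on the threshold does not trigger. All
comparisons are made on unrounded rates; the 2- and 4-decimal formats of
the reference tables are display conventions only.

Two monitoring designs are compared against that absolute benchmark: four
marked sets of five *data trees* (one set centred in each orchard
quadrant) whose fallen fruit are dissected separately, and a fixed-size
subsample of the whole-orchard *sanitation* collection.

## The synthetic orchard generator

`generate_orchard()` simulates the joint fruit-drop/infestation process on
a rectangular grid of `n_rows` by `trees_per_row` trees. For tree \(i\) in
week \(w\):

\[
X_{iw} \sim \mathrm{NB}(\mu = r_w\, g_i,\ k), \qquad
C_{iw} \sim \mathrm{Poisson}(d - r_w), \qquad
D_{iw} = X_{iw} + C_{iw},
\]

where \(X\) is the infested count, \(C\) the uninfested ("clean") drop,
\(D\) the total drop, \(d\) = `mean_drop`, \(r_w\) the weekly infestation
rate and \(k\) = `dispersion_k` (Poisson at \(k = \infty\)). The additive
decomposition makes infested fruit a subset of the drop by construction
(all infested fruit fall), and keeps both orchard means exact:
\(E[D] = d\) and \(E[X] = r_w\) for any \(k\) and any gradient. A coupling
of two *independent* processes through `min()` would instead deflate the
infested mean substantially at realistic rates (at \(d = 0.84\),
\(r = 0.1\) the loss is about 0.045, i.e. nearly half the signal), so the
additive form is the one consistent with interpreting `infestation_rate`
as the orchard-mean rate.

Tunable parameters, with the field quantities they encode:

| parameter | units | default | rationale |
|---|---|---|---|
| `mean_drop` | fruit/tree/week | 0.84 | average weekly drop recorded across the 14 trial orchards |
| `infestation_rate` | infested fruit/tree/week | — | scenario-specific; season means span 0.0001–0.21 between low- and high-pressure seasons |
| `dispersion_k` | NB shape | `Inf` | Poisson (spatially random) baseline; `k` ~ 0.1–0.5 gives the mild clumping seen in season-long fits |
| `gradient_strength` | multiplier | 0 | homogeneous orchard; > 0 elevates centres |
| `lot_size` | fruit | 20 | fruit are crated and dissected in lots of 10 or 20 |
| `n_rows`, `trees_per_row` | trees | — | trial orchards held ~500–1500 trees at 6 m × 3 m spacing |

**Spatial gradient.** The candidate mechanism for data trees
over-reading the orchard is wind shelter: oviposition is higher where
females are protected, and protection grows with the number of tree rows
between a tree and the orchard edge. The multiplier is therefore
\(g_i \propto 1 + 2s\,b_i\), where \(b_i \in (0, 0.5]\) is the tree's
normalised distance to the nearest edge and \(s\) = `gradient_strength`,
renormalised so \(\bar g = 1\) exactly (the configured rate is preserved).
A radially symmetric Gaussian bump was considered and rejected: the data
trees sit at the quadrant centres, i.e. at *mid-radius*, where a radial
bump is close to its orchard average, so it cannot reproduce the
centre-versus-whole-orchard bias the design is meant to emulate. The
edge-distance form makes every interior tree — and in particular the
quadrant centres — sit strictly above the orchard mean.

**Data trees.** `select_data_trees()` places five contiguous trees in the
middle of each quadrant: a run of five in the quadrant's central row when
the quadrant is wide enough, a vertical run when it is tall and narrow,
and a compact block around the quadrant centroid otherwise. Grids whose
quadrants hold fewer than five trees are rejected.

**Collection order.** `collect_lots()` pools fruit tree by tree in
serpentine row order (a sanitation team walking up one row and down the
next) and chunks the pooled sequence into lots of `lot_size`; the final
lot may be smaller. The field protocol only records that fruit were
crated "in the order collected", so the traversal is exposed as a config
choice (`order = "random"` re-shuffles all fruit). Within a tree the
infested/uninfested order is shuffled.

### What the generator does and does not emulate

It reproduces: grid geometry and quadrant layout, mean drop and
infestation levels, mild negative-binomial clumping, a centre-elevated
gradient, and ordered lots. It deliberately omits: weather and phenology,
moth flight and immigration, week-to-week autocorrelation beyond the
deterministic rate schedule, irregular orchard shapes, and non-FCM drop
causes as a separate class (uninfested drop is one pooled Poisson).
Passing tests on this generator show the *estimators* behave as claimed
under the stated statistical structure; they do not validate the
biological realism of any particular orchard.

One structural consequence worth knowing: conditional on lot size, fruit
infection statuses under the Poisson regime are i.i.d. Bernoulli(\(p\))
with \(p = r/d\), so per-lot counts are Binomial and their
variance-to-mean ratio is \(1 - p\) — slightly *below* 1, approaching 1
as infestation proportions get small. Tree-level clumping must overcome
this binomial-thinning deficit before lot-level ratios exceed 1, which is
why weak clumping at high infestation proportions can be invisible in
lot counts.

## Sample-size formula

`watson_n()` evaluates
\(n = \left[P(1-P) \big/ (A^2/Z^2 + P(1-P)/N)\right] / R\),
with the weekly fruit population \(N\) = area × density × drop
(`population_size()`), `P = 0.5` as the conservative variance default,
and `N = Inf` dropping the finite-population term. Results are rounded to
the *nearest* integer with ties up: this reproduces every published
worked value (239.54→240, 367.52→368, 94.96→95, 384.16→384, 96.04→96),
whereas ceiling would turn 384.16 into 385. One published figure — 78
fruit for 1.5 ha at 10% precision — is not reproducible from the formula
as stated (it gives ≈ 83) and is intentionally not asserted anywhere.

## Monte Carlo sampling coverage

For a census with `total_fruit` fruit of which `infested_fruit` are
infested, a subsample of size \(n\) drawn *with replacement* is scored
adequate when its infested proportion is at or above the lower bound of
the census's two-sided 95% confidence interval; ties count as adequate.
Coverage is the fraction of adequate iterations (default 9999), and the
*minimal adequate n* is the smallest grid size whose coverage reaches the
adequacy level (0.95, with 0.90 as the pragmatic alternative). The
original description of coverage contains a wording inversion ("one minus
the proportion ... adequately approximated"), which contradicts its own
usage where high coverage = good measurement; the implementation follows
the usage, i.e. coverage = proportion adequate.

Numerical choices:

* *With-replacement draws are Bernoulli draws.* Sampling fruit with
  replacement from a census with proportion \(p\) makes the subsample
  count exactly Binomial\((n, p)\), so `resample_adequacy()` draws
  `rbinom(iterations, n, p)`. This is not an approximation, and it gives
  an exact oracle: coverage equals the binomial tail
  \(P[X \ge \lceil n \cdot \mathrm{lower} \rceil]\), which the test suite
  checks to within 3 Monte Carlo standard errors.
* *Wilson by default.* The CI method is not pinned down by the original
  description; the Wilson score interval is the default because it is
  well behaved at small counts (and returns exactly 0 at zero counts);
  a normal (Wald) option is provided for sensitivity analysis.
* *Pooling.* The pooled curve is the mean of per-census coverages;
  censuses with identical (total, infested) pairs are computed once, so
  duplicated censuses cannot shift the pooled curve.
* Coverage curves are non-decreasing in \(n\) only up to Monte Carlo
  noise *and* integer-threshold discreteness; tests use an isotonic
  smoothing check rather than strict monotonicity.

## Dispersion and trend models

Per-lot infested counts \(y_j\) are modelled on the log scale with the
lot's fruit count as an offset:
\(\log E[y_j] = \beta_0 + \beta_1\, \mathrm{week}_j + \log f_j\).
The Poisson fit (`stats::glm`) encodes spatial randomness; the negative
binomial (`MASS::glm.nb`) encodes clumping. `dispersion_test()` compares
them by the likelihood ratio \(2(\ell_{NB} - \ell_{P})\) on 1 df —
the computation the original analysis describes, although it labels the
comparison a Wald test — and classifies *clumped* at p < 0.05. Because
the NB shape sits on the boundary of its space under the null, the df-1
reference is conservative; the type-I simulation in the acceptance tests
verifies the realised size is at or below nominal.

Boundary handling:

* all-zero data: both likelihoods tend to 0 at \(\mu \to 0\); fits are
  returned as degenerate with log-likelihood 0 and the test returns
  statistic 0, p = 1, "random";
* equi/under-dispersed data: the NB shape MLE is at \(+\infty\)
  (the Poisson special case). `glm.nb` stops at a large finite theta
  with log-likelihood marginally below the Poisson's; `fit_count_model()`
  detects this and reports the boundary fit (theta = `Inf`, Poisson
  log-likelihood), so the nesting inequality
  \(\ell_{NB} \ge \ell_{P}\) holds exactly and the LRT statistic is
  clamped at 0. `glm.nb` failures are treated the same way (a failure to
  fit clumping is no evidence of clumping);
* orchards with fewer than 2 infested fruit over the period are excluded
  from `dispersion_table()` (one infested fruit carries no dispersion
  information), and week-window fits refit from scratch on the window.

`trend_test()` fits the same offset model across orchards with orchard as
a *fixed* effect — the per-orchard tables are per-orchard anyway, and
replacing the random intercept by fixed effects keeps the estimator
closed-form GLM; mixed-model machinery is out of scope by design. The
weekly multiplicative change is \(e^{\beta_1}\) (0.87 ↔ a 13% weekly
decline) with a Wald chi-squared test.

## Protocol evaluation

`compare_protocols()` computes, per orchard-week, each set's rate
(infested on its 5 trees / 5), the pooled 20-tree rate, and the
whole-orchard rate; `table4_summary()` reduces a batch to four
percentages. Denominators: statistics (i) and (iii) are per set-week
case; (ii) is per orchard-week; (iv) is per orchard-week *with* an
orchard exceedance (0 when none occurred, so a clean season reads as "no
missed exceedance" rather than dividing by zero). Season aggregates
divide by the number of monitored weeks.

`cumulative_sample_curve()` walks the census fruit in lot order. Within a
lot the individual fruit order is not recorded, so the lot's infested
fruit are interpolated evenly (rounded); at lot boundaries — and in
particular at n = 100 with 20-fruit lots — the curve is exact, and at
n = total it closes on the census rate exactly.

## Problem sizes used in the test suite

The statistical acceptance checks run at sizes chosen to make their 3
standard-error bounds meaningful at interactive runtimes: 10,000
tree-weeks for generator means; 1000 Poisson orchard-weeks (40 lots each)
for the LRT size and 200 replicates of 300 lots at shape 0.5 for its
power; 500 replicates of an 800-tree orchard for data-tree bias (sign
test under a `gradient_strength = 3`, rate 0.2 configuration); 1000
orchard-weeks at rate 0.2 for first-100-fruit detection; and 7 orchards ×
12 weeks at a 13%/week declining rate schedule (`0.15 * 0.87^(w-1)`,
NB shape 5) for trend recovery. The "clearly above-threshold" detection
scenario uses rate 0.2 (twice the threshold): exact binomial arithmetic
shows that at rate 0.15 the first-100-fruit detection probability is only
≈ 0.88, so a ≥ 95% detection property is a statement about unambiguous
exceedances, not marginal ones.

## Known limitations

* Published per-week raw data are not available, so field results that
  depend on them (the 245/165-fruit coverage sizes, the season-specific
  trend statistics, the observed 98.41% case agreement) are emulated
  qualitatively on synthetic data, never reproduced numerically.
* The GLMM formulations of the original analysis (nested random
  intercepts, partial-R² decomposition, marginal probabilities) are
  intentionally replaced by per-orchard fits and fixed effects.
* Coverage adequacy is relative to the census's own confidence interval:
  for very sparse censuses (a handful of infested fruit) small subsamples
  can have low coverage simply because they often contain zero infested
  fruit, and near-saturated subsample sizes are needed for very tight
  censuses. Pooled minima therefore depend on the census mix.
* The serpentine traversal is an assumption about team behaviour; any
  analysis sensitive to collection order should be re-run with
  `order = "random"`.
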
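---
title: "Probabilistic age determination of tree-ring boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic age determination of tree-ring boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringdate)
```

## The problem

Classical dendrochronology assigns an exact calendar year to every tree ring
and verifies the assignment by crossdating. In many lowland tropical species
— and in unbiased "ecological" samples generally — ring boundaries range from
clearly marked to barely recognizable, false (intra-annual) boundaries are
common, and crossdating is inconclusive. Discarding such cores biases growth
estimates; forcing a year onto each boundary hides the uncertainty. ringdate
instead treats every putative boundary with explicit skepticism: the analyst
supplies, for each boundary, a probability that it is truly annual, and the
package turns those probabilities into full age distributions, confidence
curves and uncertainty-adjusted series statistics.

## The model

A core sample is an ordered set of boundaries `0..n_b-1`. Boundary 0, the
*base boundary*, has age 0 by definition and is the only boundary required to
be certain (`P = 1`); all ages are relative to it, not calendar years.
Boundary `i` closes ring `i`, so there are `n_w = n_b - 1` ring widths. Each
post-base boundary `i` carries an input probability `P_i ∈ (0, 1]` of being
annual; with probability `1 - P_i` it is false and adds no year. A *missing*
boundary — suspected where two years of growth appear as one ring — is
entered at a chosen location with its own probability and participates in the
identical arithmetic: if present, it is necessarily annual.

The age `A_i` of boundary `i` is then a sum of independent Bernoulli
indicators, computed by the recursion

> `L[i+1, a] = (1 - P[i+1]) * L[i, a] + P[i+1] * L[i, a-1]`,

starting from a point mass at age 0. Two exact consequences anchor every
computation and are used as built-in self-checks:

* **cumulative-probability identity**: `E(A_i) = Σ_{j ≤ i} P_j` — the
  expected age advances by exactly the probability of each boundary;
* **independent-increment variance**: `Var(A_i) = Σ_{j ≤ i} P_j (1 - P_j)`.

When all uncertain boundaries share one probability the distribution is a
shifted binomial, which `binomial_ages()` provides as a closed-form
cross-check of the general recursion.

## Confidence limits

Ages are modelled in whole years, but time is continuous, so non-integer
confidence limits are meaningful. `inverse_cdf()` connects the knots
*(cumulative probability through age a, a)* — cumulative probability
**inclusive** of the age's own mass — by straight lines and reads quantiles
off that piecewise-linear function. When the lower-tail quantile falls below
the first knot's cumulative probability, no leftward interpolation exists and
the lowest possible age is substituted. This knot convention was fixed by
validating the resulting limits against the method's reference dating table
at two decimals and is frozen in regression tests; the upper limit is always
interpolable because the last knot sits at cumulative probability 1.

`growth_curve()` pairs each boundary's cumulative radius with its expected
age and limits. The three curves share the radius axis and end at the maximum
*measured radius* (not a maximum age); zero-width rings and inserted
overlapping boundaries produce vertical steps.

Because the age distribution is discrete, the interpolated 95% interval does
not cover the (integer) realized age with probability exactly 0.95: the
coverage is `F(⌊upper⌋) - F(⌈lower⌉ - 1)`, which can fall short of the
nominal level by at most the probability mass at the ages the endpoints cut
through. For a 50-boundary series with `P = 0.8` throughout, the analytic
coverage is 0.934. The Monte-Carlo tests therefore compare empirical coverage
against this analytic value (within simulation error) and check the
discreteness bound, rather than asserting 0.95 exactly.

## Series statistics

The classical mean sensitivity

`ms = mean over i of |2 (w[i+1] - w[i]) / (w[i+1] + w[i])|`

ranges from 0 (constant widths) to 2 (alternation with zero). Each term
couples two rings across their *shared* boundary; if that boundary is annual
only with probability `P`, the term's expectation is scaled by `P`, giving
the probabilistic mean sensitivity, its variance (`E(X²) - E(X)²` with the
same weights), a standard error (variance divided by `n_w`), and a
normal-approximation interval with the fixed 1.96 multiplier.

For the lag-1 autocorrelation and time-series variance (division by `n_w`,
not `n_w - 1`), the probability weighting follows the index convention that
uniquely reproduced the method's reference case-study values: cross terms
`(w_i - w̄)(w_{i+1} - w̄)` are weighted by the shared boundary's probability,
squared deviations `(w_i - w̄)²` by the ring's *inner*-boundary probability,
so ring 1 carries the base boundary's certain weight. The mean `w̄` is the
plain arithmetic mean — no probability-weighted mean is defined. The process
standard deviation `s_proc = sqrt(s_ts² / (1 - r²))` combines variance and
persistence; probabilistic statistics never exceed the classical ones and
coincide with them when every `P = 1`.

Stationarity is assumed; `detrend_check()` runs an advisory OLS slope test of
width on ring number and `series_stats()` warns (but never detrends) when the
slope is significant, mirroring how the method itself treats the check.

## Missing boundaries

Missing boundaries cannot be assigned a probability at an observed location;
one computes an expected count from a frequency `F` per recognizable boundary
(`expected_missing()`), flags candidates in unusually wide rings by
studentizing the widths against a t distribution with `n_w - 1` degrees of
freedom (`detect_wide_outliers()`; one-sided upper tail by default, since
missing boundaries hide in *wide* rings), splits the expected count evenly
over the candidates (`candidate_probability()`, capped at 1), and inserts
each as a midpoint split of its ring into equal halves
(`insert_missing()`; alternative split fractions are available but never the
default). Location uncertainty of an inserted boundary is deliberately
unmodelled — only its existence is probabilistic. Insertion conserves total
radius exactly and, by the cumulative identity, raises the final expected age
by exactly the sum of inserted probabilities.

## Synthetic data and what it does (not) show

`random_series()` draws independent uniform probabilities and widths; its
defaults — probabilities on [0.5, 1], widths on [0, 0.5] cm, 301 boundaries
for the long scenario — are the conditions of the method's own sensitivity
simulations, and `make_scenario()` builds the four standard perturbations
(certain midpoint-split missing boundaries; all probabilities 0.5; all 0.95;
the long random series). `simulate_true_ages()` samples the exact generative
story the recursion marginalizes — each boundary independently annual with
its probability — so simulated "true" ages are known by construction and
coverage can be measured honestly.

What passing these tests shows is internal consistency of the probability
model, not field validity: real cores have serially correlated widths, age
trends, analyst-dependent recognizability, and input probabilities that are
themselves estimates (e.g. 0.83 from 1861 crossdated rings of a neighbouring
species). The generator emulates none of these; in particular it cannot
validate a chosen `P`, only what follows from it.

## Numerical choices

* Distributions are stored densely over their support; leading/trailing mass
  below 1e-15 is trimmed and the rest renormalized. This keeps the recursion
  exact after `P = 1` steps (whose leading entry is exactly 0) and avoids
  carrying dead tails in long series. Double precision suffices at realistic
  lengths; no log-space accumulation is needed.
* The reported possible-age *range* is the theoretical one (minimum = number
  of certain boundaries so far, maximum = the boundary number), independent
  of numerical trimming.
* Normalization is asserted to 1e-9; the cumulative-probability identity to
  1e-9 in tests and 1e-6 in the CLI self-check, which aborts on mismatch.
* Mean sensitivity is undefined when two consecutive widths are both zero
  (0/0); this raises an error rather than a silent drop.
* Problem sizes in the test suite: exhaustive enumeration up to 15 uncertain
  boundaries (2^15 outcomes), 100 random series for the identity checks, and
  10^4 replicates for coverage — all chosen to keep the full suite under a
  minute while leaving the Monte-Carlo error well below the tolerances
  tested.

## Known limitations

Calendar-year anchoring, crossdating, image-based boundary detection and
detrending/standardization pipelines are out of scope. Input probabilities
are taken as given, without sampling uncertainty; the confidence limits
therefore reflect only the boundary-existence uncertainty the model encodes.
The methods extend naturally to any periodically marked accretionary tissue
(fish otoliths, bivalve shells, coral bands), but nothing here is specific to
those systems.
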
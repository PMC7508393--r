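# ringdate

Probabilistic age determination for tree-ring series.

In many woody species and sites — above all in the lowland tropics — ring
boundaries cannot be verified by crossdating: some are clearly annual, others
may be false (intra-annual), and whole boundaries may be missing in
unusually wide rings. ringdate is for dendrochronologists and forest
ecologists who would otherwise have to discard such cores. Instead of forcing
an exact year onto every boundary, the analyst supplies an *input
probability* `P_i ∈ (0, 1]` that boundary `i` is truly annual, and the
package computes everything that follows.

## The method

Ages are counted in years from the *base boundary* (boundary 0, age 0 by
definition). The age of boundary `i` is the sum of independent Bernoulli
indicators, obtained by the recursion

```
L[i+1, a] = (1 − P[i+1]) · L[i, a] + P[i+1] · L[i, a−1]
```

starting from a point mass at age 0. Two exact identities follow and serve as
built-in self-checks:

- `E(A_i) = Σ_{j≤i} P_j` — expected age advances by each boundary's probability;
- `Var(A_i) = Σ_{j≤i} P_j (1 − P_j)`.

Confidence limits come from a piecewise-linear interpolation of the discrete
inverse CDF (knots at the inclusive cumulative probabilities, lower-bound
substitution when the lower tail is not interpolable). On top of this the
package provides radius-versus-age confidence curves, probabilistic versions
of the classical series statistics (mean sensitivity `ms`, lag-1
autocorrelation `r_ac1`, time-series variance `s²_ts`, process standard
deviation `s_proc = √(s²_ts/(1−r²_ac1))`), expected-missing-boundary
accounting with studentized-width outlier detection, and scenario
simulation. See the vignette `vignettes/probabilistic-ring-dating.Rmd` for
the full account.

## Worked example

A 49-boundary core where every post-base boundary is recognizable with
probability 0.83 (the package's running case study):

```r
library(ringdate)
s <- ring_series(c(1, rep(0.83, 48)))
summ <- summarize_series(s, level = 0.95)
tail(summ, 3)
```

```
 boundary_index p_annual min_age max_age mean_age sd_age ci_lower ci_upper
             46     0.83       0      46    38.18  2.548    32.34    42.40
             47     0.83       0      47    39.01  2.575    33.15    43.26
             48     0.83       0      48    39.84  2.602    33.96    44.10
```

The last boundary could be anywhere from 0 to 48 years old, but its expected
age is 39.84 years (= 0.83 × 48, by the cumulative identity) with standard
deviation 2.60 and 95% confidence interval (33.96, 44.10). With measured
widths the same series also yields the uncertainty-adjusted statistics:

```r
set.seed(8)
s2 <- ring_series(c(1, rep(0.83, 48)), width_cm = runif(48, 0.05, 0.42))
series_stats(s2)
```

```
Series statistics (n_w = 48)
  mean sensitivity      ms  = 0.584   probabilistic = 0.484 (SE 0.0561, CI 0.375..0.594)
  lag-1 autocorrelation r   = -0.166   probabilistic = -0.166
  time-series variance  s2  = 0.01020 cm2 probabilistic = 0.00847 cm2
  process SD            s   = 0.1024 cm  probabilistic = 0.0933 cm
```

The probabilistic values are always at most the classical ones: doubtful
boundaries shrink the evidence each width pair contributes.

A command-line wrapper is installed at `inst/cli/ringdate`:

```sh
Rscript inst/cli/ringdate date --level 0.95 --out ages.csv input.csv
Rscript inst/cli/ringdate stats input.csv
Rscript inst/cli/ringdate detect-missing --freq-missing 0.02 input.csv
Rscript inst/cli/ringdate simulate --scenario d --seed 1 --out sim.csv
```

Input CSVs have columns `index,type,probability,width_cm` with boundary types
base/annual/recognizable/missing.

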
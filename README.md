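# dosesearch

Sequential design of drug-combination experiments. Given `n` drugs, each
discretized into concentration levels `0..T`, the package searches the
`(T+1)^n` lattice of cocktails for a combination within 95% of the maximum
sensitivity while spending as few experiments (oracle queries) as possible —
the setting of personalized combination screens, where every query is a
wet-lab measurement and exhaustive testing is out of the question.

It is written for computational biologists and screening groups who need a
derivative-free sequential search that works on unnormalized response
surfaces, plus the analytic machinery to predict how fast such a search
should close in on the optimum.

## Method

The **diverse stochastic search (DSS)** runs in two phases:

1. **Initialization** — `m` maximin Latin-hypercube points snapped to the
   grid and measured in parallel, giving homogeneous first coverage.
2. **Iterative segment** — per experiment: min–max normalize the
   measurements and raise them to the power `n − 1`; estimate the full
   response surface by penalized least squares in the DCT domain
   (minimizing `‖W^(1/2)(ŷ − y)‖² + s‖Dŷ‖²` with a 0/1 reliability weight
   `W` and the Neumann-boundary Laplacian `D`); then with probability 0.3
   take a *focused* step (propose the highest-ranked untested point, with
   steepest-ascent hill labelling, discovered-hill skipping and suppression
   of over-explored peaks) and otherwise a *diverse* step (Gibbs-sample the
   estimated surface as an unnormalized pmf and measure one untested draw).

The package also implements the exact theory of the minimum L1 distance
between tested points and the optimum: per-axis pmf
`f_W(w) = 2(T+1−w)/(T+1)²` (`f_W(0) = 1/(T+1)`), its `n`-fold convolution
`R1`, the minimum-of-`m` order statistic
`CDF_R2(x) = 1 − (1 − CDF_R1(x))^m`, the `k`-optimum reduction
`μ_k(n,T,m) = μ(n,T,km)`, and the focused-refinement decay `D/2^ρ₁` from a
product of uniform shrinkage factors. A benchmark harness measures search
cost and success rate over repeated seeded runs against a matched
random-sampling control.

## Worked example

```r
library(dosesearch)

s <- builtin_sphere_surface()            # 21 x 21 unimodal test surface
fit <- dss_search(s, m = 5, max_steps = 60, seed = 1)
summary(fit)
#> 60 experiments (5 initialization + 55 sequential)
#>   best sensitivity 1.0000 of max 1.0000; final min L1 distance to optimum: 0
#>   reached 95% of max at experiment 3
#>   steps by path:
#> diverse focused     lhs
#>      39      16       5
coef(fit)                                # best cocktail found
#> d1 d2
#> 10 10
```

The summary says the run spent 5 initialization and 55 sequential
experiments, that a cocktail within 95% of the maximum was already measured
at experiment 3, and that the search ended on the exact optimum (final L1
distance 0). Over repeated runs:

```r
dss_benchmark(builtin_sphere_surface(), n_runs = 100, budget = 250,
              m = 5, base_seed = 1)
#> DSS benchmark: 100 runs, budget 250, threshold 0.95 x max
#>   cost 8.24 (sd 5.87), worst case 27, success rate 100%
```

i.e. 8.24 experiments on average to reach 95% of the maximum — against 441
for exhaustive search and 11.6 expected for uniform random sampling on this
surface. The analytic side:

```r
min_distance_table(n = 5, T = 10, m = c(20, 40, 60))
#>   n  T  m     mean variance
#> 1 5 10 20 8.147817 5.250334
#> 2 5 10 40 6.861313 3.708254
#> 3 5 10 60 6.208944 3.059142
```

the exact expected L1 distance from the optimum to the closest of `m`
uniformly placed cocktails — 6.86 for `m = 40` — with its variance.

Measured two-drug response matrices (e.g. percent inhibition) can be loaded
with `read_surface()`; a small synthetic example ships in
`inst/extdata/synthetic_inhibition_9x9.csv`. A thin command-line front end
with `theory-table`, `run` and `benchmark` subcommands is in
`inst/cli/dosesearch.R`.

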
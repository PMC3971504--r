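---
title: "Sequential search for optimal drug-combination doses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential search for optimal drug-combination doses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosesearch)
```

## The problem

Combination therapy screens ask for the concentrations of $n$ drugs that
maximize a measured response (cell inhibition, bacterial growth suppression,
...). Each candidate cocktail requires a wet-lab experiment, and the number
of candidates explodes: with each drug discretized into levels $0..T$, the
search space $\Omega$ holds $(T+1)^n$ cocktails. Exhaustive screening of
$11^5 \approx 161{,}000$ combinations is not an option, and because drug
synergies vary between patients and cell lines, prior response models cannot
be trusted. The quantity to minimize is therefore the *number of sequential
experiments* (oracle queries) needed to find a cocktail within 95% of the
maximum sensitivity — not CPU time.

`dosesearch` implements a diverse stochastic search (DSS) over the index
lattice. A cocktail is an integer vector $V$ with $V(i) \in \{0,\dots,T\}$;
the oracle is a function $f:\Omega \to [0,1]$ and every call to it is
counted. Real concentrations are an affine view of the indices
(`index_to_concentration()`); all of the algorithm and all of the distance
theory live on the lattice.

## The algorithm

**Step 1 — parallel initialization.** $m$ points are drawn as a maximin
Latin hypercube in $[0,1]^n$ (`generate_maximin_lhs()`) and snapped to the
nearest grid points (`snap_to_grid()`). The Latin hypercube property places
one point in each of $m$ equal strata per dimension; the maximin criterion
(largest minimum pairwise distance) spreads them homogeneously, so no part
of the space is left unobserved. These $m$ cocktails are measured up front.

**Step 2 — iterative segment.** Each subsequent experiment is chosen by:

1. Min–max normalize all measurements to $[0,1]$ and raise them to the
   power $n-1$ (`normalize_and_power()`). The powering sharpens peaks
   relative to average responses, which matters in higher dimensions where
   the diverse path samples from this surface.
2. Estimate the response at *every* grid point from the measured ones by
   penalized least squares in the DCT domain (`estimate_surface()`, below).
3. With probability `p_focus` (default 0.3) take a **focused** step,
   otherwise a **diverse** step.

The *focused* path walks the sorted (experimental and estimated)
sensitivities from the top and proposes the first estimated — that is, not
yet measured — point that does not lie on an already "discovered" hill.
Hills are identified on the estimated surface by steepest ascent
(`ascent_path()`): two points belong to the same hill when their ascent
walks terminate at the same local maximum. A hill whose top
`cluster_threshold` points are all experimental is marked discovered —
enough is known about it, and the walk skips its remaining points. If the
walk inspects `cluster_break` points without finding a candidate, the
current peak is over-explored: all estimates inside a small sphere around it
(volume `cluster_sphere_fraction` of the search space) are zeroed, their
values archived, and the iteration restarts. A suppressed sphere is restored
as soon as a new measurement lands inside it.

The *diverse* path treats the (non-negative, peak-emphasized) estimated
surface as an unnormalized probability mass function and draws
`gibbs_points` samples from it by systematic-scan Gibbs sampling
(`gibbs_sample()`); one untested sample is selected uniformly as the next
experiment. Sampling — rather than maximizing — is what lets the search
jump between distant candidate hills instead of creeping along gradients.

No grid point is ever measured twice: the focused candidate is untested by
construction and the diverse path resamples (or falls back to a uniform draw
over untested points), since re-measuring wastes an experiment under the
cost metric.

## Surface estimation

The full-grid estimate $\hat y$ minimizes

$$F(\hat y) = \lVert W^{1/2}(\hat y - y)\rVert^2 + s\,\lVert D \hat y\rVert^2,$$

where $y$ holds the measured values (0 at untested points), $W$ is a
diagonal 0/1 reliability weight (1 at experimental points), $s$ is the
smoothing parameter, and $D$ is the $n$-dimensional second-difference
operator with Neumann (reflective) boundary. The DCT-II diagonalizes $D$,
with eigenvalue tensor
$\Lambda_{k_1\dots k_n} = \sum_i \left(2 - 2\cos(\pi k_i/N_i)\right)$
(`penalty_eigenvalues()`), so the minimizer is reached by the fixed-point
iteration

$$\hat y \leftarrow \mathrm{IDCT}\!\left[\Gamma \odot
  \mathrm{DCT}\!\left(W \odot (y - \hat y) + \hat y\right)\right],
  \qquad \Gamma = \frac{1}{1 + s\Lambda^2}.$$

The transforms are applied axis-by-axis with exact orthonormal cosine
matrices (axis sizes here are small, typically 11–21, so this is both exact
and fast). `brute_force_smoother()` solves the same normal equations
$(W + sD^\top D)\hat y = Wy$ densely and is the reference the test suite
checks the iteration against (agreement to $10^{-6}$ and better).

Numerical choices, where the formulation leaves them open:

* **Initialization.** The iteration starts from a nearest-known-neighbour
  fill rather than zeros: with the iteration count fixed at 100 a good start
  matters, and the fill is linear in the data so the estimator stays linear.
* **Early stop.** Iterations also stop once $\max|\Delta \hat y| < 10^{-9}$.
* **Smoothing.** Default $s = 10^{-3}$: small enough that the estimate
  passes through the experimental points (the deviation at measured points
  scales linearly with $s$), large enough to regularize the many unobserved
  modes. No generalized cross-validation is attempted — the search wants an
  interpolant, not an optimal smoother.
* **Clipping.** Estimates are clipped at 0 before use as a sampling
  distribution; the smoother can undershoot below 0 between measurements.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 5 (2 drugs), 3 (tabulated 2-drug), 10 (3–5 drugs) | initialization experiments |
| `p_focus` | 0.3 | probability of the focused path per iteration |
| `power_exponent` | $n-1$ | peak emphasis of normalized measurements |
| `cluster_threshold` | $2n-1$ if $n<5$, else 7 | experimental points before a hill is discovered |
| `cluster_break` | $\lceil 1\%$ of grid$\rceil$ | sorted-walk budget before suppression |
| `cluster_sphere_fraction` | 1/500 | suppressed-sphere volume fraction |
| `gibbs_points` | $2\times$ grid size if $<7500$, else 15000 | samples per diverse step |
| `smoothing` $s$ | $10^{-3}$ | smoother penalty weight |
| `smoother_iterations` | 100 | smoother iteration budget |

All are exposed through `dss_params()`. With $n = 2$ the power exponent is
1, i.e. no emphasis — accepted as the natural continuation of the $n-1$
rule. For a constant measurement vector (possible in the first iterations of
a flat region) the normalization is degenerate; it maps to all ones, which
makes the subsequent sampling uniform — the least informative, and therefore
least committal, choice.

## Distance theory

How close should the best initial point land to the optimum? With both a
test cocktail and the optimum $V_{\max}$ placed uniformly on the lattice,
the per-drug signed difference $Z = V(i) - V_{\max}(i)$ has the triangular
pmf $f_Z(z) = (T+1-|z|)/(T+1)^2$ on $-T..T$, and its absolute value $W$
folds this to $f_W(0) = 1/(T+1)$, $f_W(w) = 2(T+1-w)/(T+1)^2$. The L1
distance $R_1$ of one point is the $n$-fold convolution of $f_W$
(`l1_distance_pmf()`), and the distance of the closest of $m$ points follows
from the minimum order statistic,
$\mathrm{CDF}_{R_2}(x) = 1 - (1-\mathrm{CDF}_{R_1}(x))^m$
(`min_l1_distance_pmf()`). All pmfs are computed by direct convolution —
no FFT round-off — and the test suite verifies an 18-row reference lattice
of means and variances to two decimals, e.g. a mean of 6.86 for
$n=5$, $T=10$, $m=40$.

With $k$ well-separated optima the minimum is over $k \cdot m$ distances, so
`multi_optimum_moments(n, T, m, k)` simply delegates to $m' = k m$. Each
focused refinement near the optimum multiplies the remaining distance by an
(approximately) uniform factor on $(0,1)$; a product of $\rho_1$ uniforms
has density $(\ln(1/x))^{\rho_1 - 1}/(\rho_1-1)!$ and mean $2^{-\rho_1}$, so
an initial expected distance $D$ shrinks to $D/2^{\rho_1}$
(`expected_distance_after_focus()`). `theoretical_trajectory()` stitches the
two regimes: exact minimum-of-$m'$ means during initialization, geometric
decay with $(\text{iter}-m)\,p_{\text{focus}}$ expected refinements after.

Two caveats, both visible in the package's own checks. The order-statistic
step treats the $m$ distances to a shared optimum as independent — they are
only conditionally independent — which biases the analytic mean slightly
low of the true i.i.d.-uniform value. More importantly, the algorithm's
Step 1 is a *maximin Latin hypercube*, not an i.i.d. uniform draw: a
stratified, spread-out design covers the space better, so its minimum
distance to the optimum runs *below* the analytic curve, increasingly so for
small $m$ in low dimension. The package therefore checks the analytic band
where the approximation is meant to hold — many initial points, moderate
dimension, optimum placed uniformly ($n=4$, $T=10$, $m=40$ in the test
suite) — and treats the analytic curve as an upper envelope, not an exact
prediction, for very small designs such as $m=5$ in two dimensions.

## What the synthetic surfaces emulate — and what they do not

`hill_surface()` builds a floor plus Gaussian hills, clipped at 1; the hill
count, widths and heights control how many near-optimal points exist (from
an isolated optimum to broad plateaus), which is the feature that dominates
search cost. `inverted_sphere_surface()` is the smooth unimodal benchmark;
`builtin_sphere_surface()` fixes it on a 21×21 grid with the peak at
(10, 10). `read_surface()` ingests measured two-drug response matrices
(e.g. percent inhibition, rescaled by the file maximum — measured screens
rarely state their normalization, so division by the observed maximum is
the package's convention).

Real dose-response surfaces are not sums of isotropic Gaussians: they show
ridge-like synergy bands, plateaus at saturating doses, and — crucially —
measurement noise, which the oracle here does not model (each cocktail has
one exact sensitivity). Passing benchmarks on these generators shows that
the search machinery works as specified on smooth multi-modal landscapes;
it does not certify behaviour under assay noise or strongly anisotropic
interactions.

## Benchmarking conventions

`dss_benchmark()` repeats the search over consecutive seeds and reports
*cost* (mean experiments until a measurement reaches `threshold` × max,
default 0.95), its standard deviation, the worst case, and the *success
rate* within the budget. Initialization experiments count toward cost.
`random_search_baseline()` is the matched control — uniform sampling
without replacement, expected cost $(N+1)/(q+1)$ with $q$ qualifying points
among $N$ — and the test suite requires DSS to beat it on the built-in
surface. Identical seeds give byte-identical results; the run-level RNG
stream is consumed in a fixed order (initial design, path choices, Gibbs
draws, candidate selection).

Problem sizes in the shipped tests were chosen to exercise every code path
at desk scale: smoother cross-checks on grids up to $11^2$, Gibbs
diagnostics at $10^4$ samples, 100-run benchmarks on the 21×21 surface, and
the analytic-band check at $n=4$, $T=10$, $m=40$ (initialization phase
only, which is what the band describes).

## Known limitations

* Dense full-grid tensors bound the practical dimension to roughly
  $n \le 6$ at 11 levels; the intended use is optimizing concentrations
  *after* the candidate drugs have been narrowed to a handful.
* No measurement-noise model and no toxicity/cost term in the objective.
* Hill identities are recomputed on the current estimate each focused pass;
  labels are meaningful within a pass, not stable across a whole run.
* Exact plateaus (tied estimates) can split one flat hill into several
  ascent sinks; with continuous-valued estimates ties are measure-zero.

## A worked call

```{r}
s <- builtin_sphere_surface()
fit <- dss_search(s, m = 5, max_steps = 60, seed = 1)
summary(fit)
```

```{r}
min_distance_table(n = 5, T = 10, m = c(20, 40, 60))
```
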
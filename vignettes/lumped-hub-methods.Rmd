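---
title: "Hubs as feedback: methods behind hubnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hubs as feedback: methods behind hubnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

hubnet studies binary threshold networks: `N` units `s_i` taking values in
`{-1, +1}` (expressed/repressed genes, firing/quiescent neurons), updated by
the sign of their summed weighted input,

```
s(t + 1) = sign(W s(t)),
```

where row `i` of `W` lists the inputs of node `i`. The weight matrix is a
Hadamard product `W = T * J` of a 0/1 topology `T` drawn from a degree
ensemble and i.i.d. standard-Gaussian strengths `J`. The scientific question
is how the *shape* of the degree distribution — specifically the presence of
a few massive **outgoing** hubs, the master regulators of gene-network
biology — controls whether the dynamics settles into a (quasi-)fixed point
or wanders chaotically.

The package's organizing idea is that a finite scale-free network is
dominated by a handful of hubs, so it can be approximated by a **single
effective hub** coupled to a homogeneous bulk, and that this hub acts like
an *external drive* that can suppress chaos — turning topology into a
feedback-control problem.

## Ensembles and conventions

* **SFO**: out-degrees drawn from a discretized Pareto law
  `P(k) ~ k^-gamma` (`gamma > 2`, location `k_min`), targets chosen
  uniformly; in-degrees come out binomial-like. **SFI** is its transpose.
  **Binomial**: every directed pair independently with probability `p`.
* Continuous Pareto draws are rounded half-away-from-zero and clamped to
  `[1, N - 1]`; with `k_min = 0.5` the bottom half-interval maps to degree
  1. Self-loops and multi-edges are excluded everywhere (the generated hubs
  then have degree strictly below `N`, matching the simple-graph reading of
  "a set of k random outgoing connections").
* Orientation is fixed package-wide: `T[i, j] = 1` means `j -> i`, so the
  local field is literally `W %*% s`, and out-degrees are column sums. The
  convention matters only because it is easy to get silently wrong; it is
  therefore stated on every container.

## Dynamics protocol

Updates are asynchronous: each step a fresh uniform subset of
`round(0.1 N)` distinct nodes recomputes its sign simultaneously
(`update_fraction = 1` recovers the synchronous map). The standard
measurement protocol is a 4000-step burn-in followed by a 1000-step window;
a node is **frozen** iff its value never changes during the window, the
frozen core (FC) is the frozen fraction, and a state is a **quasi-fixed
point** (QFP) when FC >= 0.9 (fixed point when FC = 1). The 0.9 threshold
is where the FC distribution develops its near-1 mode; it is a parameter
(`qfp_threshold`) rather than a constant. Convergence probabilities are
fractions of independent (topology, strengths, initial state) realizations
reaching the criterion, with binomial standard errors.

Two sign conventions are provided. The default `sign(0) = 0` prunes
zero-input nodes (they lock at 0); the `"positive"` variant maps a zero
field to +1, so source nodes become a constant drive. All headline results
use the default; the variant exists because the choice measurably shifts
stability for very sparse bulks.

The compiled simulator keeps the field `x = W s + b` incrementally (one
sparse column walk per actual flip), so a 5000-step run at `N = 1500` costs
milliseconds; trajectories are recorded only on request. Frozen-core
bookkeeping is change-tracking, equivalent to comparing every recorded
window state, and reported quantities are independent of whether the
trajectory is stored.

## The lumped-hub reduction

Given a topology and a lumping count `m` (default 4), the `m` largest
out-degree nodes (ties to the lowest index) are merged into one effective
hub and the rest — the bulk — is *redrawn* as a binomial network with the
original mean bulk degree `k_b`. Three levels of coarse-graining for the
hub's outgoing vector `u`:

1. **Exact pattern** — `u_i ~ N(0, c_i)` where `c_i` counts the lumped hubs
   pointing at bulk node `i` (summing independent unit-variance strengths);
   nodes missed by all hubs keep `u_i = 0`.
2. **Sparse Gaussian** — only the statistics survive:
   `u_i ~ N(0, sigma_h^2)` with probability `alpha`, else 0, where
   `alpha` is the fraction of bulk nodes targeted and `sigma_h^2` the mean
   connection count over targeted nodes (second-moment matching,
   conditional on being connected — the estimator is the package's choice,
   as only the matching principle is fixed by the construction).
3. **Dense Gaussian** — sparseness discarded: `u_i ~ N(0, alpha sigma_h^2)`
   for all `i`. Total output variance matches level 2, yet this level
   systematically overestimates convergence; keeping `alpha` explicit is
   the point of the three-parameter description `(k_b, sigma_h, alpha)`.

The hub's incoming vector `v` is supported on the union of the `m` hubs'
bulk in-neighbors (exact pattern) or on `round(k_h)` random bulk nodes
(Gaussian levels), with i.i.d. `N(0, 1)` strengths; `k_h` is the lumped
in-degree, typically `m <k>`. Hub-to-hub edges among the lumped hubs are
discarded — neglecting their internal dynamics is exactly the approximation
being made, and its breakdown (heavy tails, `gamma` near 2.2, where the
derivative depends strongly on `m`) is diagnosable with
`lumping_sensitivity()`.

**Open loop** clamps the hub at +1, making `u` a constant bias on the bulk;
**closed loop** restores the hub as dynamical node `n_bulk + 1`.

## Mean-field damage spreading

Chaos is probed by the normalized Hamming distance `d(t)` between two
trajectories. Within mean-field theory its one-step map has derivative at
the origin

```
grad_d = (2 k_b / pi) * sum_{k' >= 0} Pois(k'; k_b) *
         [ alpha * atan(1 / sqrt(k' + sigma_h^2))
           + (1 - alpha) * atan(1 / sqrt(k')) ]
```

— the expected number of rows whose sign a single flipped input overturns.
Each row with `k'` other inputs contributes the folded-Gaussian exceedance
`Pr(|z1| > eta |z2|) = (2/pi) atan(1/eta)`; the `k' = 0` term takes its
limit `pi/2` (an undriven isolated input always propagates damage).
Convergence under the clamped hub requires `grad_d < 1`; solving
`grad_d = 1` in `sigma_h` gives the critical hub strength
`sigma_crit(k_b, alpha)`, with the dense-hub (`alpha = 1`) large-`k_b`
asymptote `2 k_b / (pi sqrt(k_b + sigma_h^2))`, hence the asymptotically
linear critical line `sigma_crit ~ (2/pi) k_b`. For sparse hubs
(`alpha < 1`) there is a maximal bulk degree beyond which *no* hub strength
suppresses chaos; `sigma_crit()` then returns `NA` rather than erroring,
since "undefined" is a legitimate region of the phase diagram.

Closing the loop: the clamped value is consistent with the hub's own input
with probability 1/2, and the fixed point survives if the bulk converges
before the hub flips, `T_conv < T_flip` with
`T_conv = -log(N delta) / log(grad_d)` and `T_flip = N / (k_h delta)`
(natural logarithms throughout; the near-critical margin is
`1 - grad_d > (k_h delta / N) log(delta N)`). Away from criticality the net
effect is the **factor-of-half rule**: closed-loop convergence probability
is half the open-loop one.

`grad_d_oracle()` estimates the same derivative with no mean-field input:
flip one random bit of a random state, advance both copies one synchronous
step, count differing bits. Analytic and Monte-Carlo routes are kept
strictly separate so each can validate the other.

## Fixed-point censuses

For dense networks up to `n = 24`, `enumerate_fixed_points()` checks all
`2^n` states exactly, walking a Gray code so each state costs one column
update of the field. The census ensemble is fully connected with i.i.d.
`N(0, 1/n)` entries — *including* the diagonal — and, when driven, a dense
standard-Gaussian vector `u` scaled by `sigma_h` inside the threshold. The
`1/n` normalization puts the recurrent input on unit scale so that
`sigma_h` measures the drive against it; with unnormalized weights the same
`sigma_h` values describe a drive weaker by `sqrt(n)` and the census
distribution is very different. Both conventions were compared during
development; the normalized, diagonal-included ensemble is the one whose
census the acceptance suite validates.

Undriven fixed points come in `+-s` pairs, so `M` is even realization by
realization and the reference law is paired Poisson, `M/2 ~ Poisson(1/2)`;
a weak drive unpairs them (`M ~ Poisson(1)`). Both references have mean
exactly 1 — the general expectation result for this function ensemble — and
the empirical mean matches it, but the *distribution* at `n = 16` deviates
beyond standard error (e.g. the empty-census probability exceeds the paired
reference's `exp(-1/2) = 0.607`). That gap is a finite-size property of the
system, documented and asserted as such; the package intentionally
reproduces it rather than treating it as an implementation error.

## Trajectory statistics

For non-converging runs the package computes the participation ratio
`(tr C)^2 / tr(C^2)` of the state covariance (effective dimensionality) and
the node-averaged temporal autocorrelation, with a log-linear exponential
fit over lags 0–5 and an "asymptotic" level defined as the mean over the
last quarter of lags. Ensemble averages filter to trajectories with
asymptotic autocorrelation below 0.3, which removes frozen and near-frozen
runs. Autocorrelation subtracts each node's temporal mean by default (the
standard definition); a raw-product option exists because the ±1 states
make the unsubtracted version meaningful too. When sampling trajectories
generated with 10% asynchronous updates, statistics should be computed on
states taken once per sweep (`1 / update_fraction` steps): consecutive raw
steps are trivially correlated because 90% of nodes cannot have moved.

## Numerical choices

* Poisson series in `grad_d` truncated at residual tail mass `1e-12`
  (`qpois` upper tail), replacing an unspecified cutoff with a spectrally
  accurate one.
* `sigma_crit` brackets by doubling and bisects to `|grad_d - 1| < 1e-8`;
  deterministic, no derivative needed.
* Degree rounding is half-away-from-zero; update subsets are drawn without
  replacement by partial Fisher–Yates from R's RNG stream, so every result
  is reproducible from a single `seed` argument (`withr::local_seed`
  keeps the caller's RNG state untouched).
* Enumeration exactness is independent of batching; states with a zero
  field component are non-fixed by construction.
* Hub selection ties break to the lowest index; all "undefined" outcomes
  (no critical strength, zero covariance participation ratio) are `NA`
  values, not errors.

## What the generators do and do not emulate

The synthetic ensembles implement the study conditions themselves: the
degree laws, Gaussian strengths, update protocol and drive conventions
above. They do not emulate degree correlations, prescribed joint in/out
sequences, modularity, signed-interaction structure, or any empirical
gene-regulatory wiring. A passing suite therefore certifies the model's
internal machinery — generation, reduction, theory, enumeration — on its
own terms; it does not certify that any particular biological network is
described by these ensembles.

## Problem sizes used by the test suite

The suite favors a few deep checks at sizes a laptop handles comfortably:
censuses at `n = 16` with `10^4` realizations per drive level; the
mean-field/oracle comparison on `N = 5000` sparse-Gaussian systems (13
parameter points, 3 networks x 250 trials each); phase-transition and
factor-of-half scans at `N = 1500` with 100–200 realizations per point;
the SFO/SFI contrast at `N = 1000` with 200 realizations per ensemble; and
the coarse-graining ladder at `N = 1500` with 120 realizations per level
and exponent. Binomial error bars are carried everywhere so the scaled-down
comparisons remain statistically honest.

## Known limitations

* For `gamma` near 2.2 the reduction is sensitive to the lumping count and
  the lumped ensemble drifts from the original — a real limit of the
  approximation, not a bug; `lumping_sensitivity()` makes it visible.
* For strongly sparse hubs (small `alpha`, large `gamma`) the mean-field
  transition prediction degrades; the phase diagram marks the region where
  no critical strength exists.
* The census theory assumes orthogonality of chaotic trajectories, which
  `n <= 22` cannot deliver; expect distributional gaps at enumerable sizes.
* Exhaustive enumeration refuses `n > 24`; sampling-based fixed-point
  search is out of scope.
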
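# hubnet

Heterogeneous biological networks — gene regulatory circuits, neural
wiring — typically have a heavy-tailed *outgoing* degree distribution: a
few master regulators touch hundreds of targets while every gene is
regulated by only a handful of inputs. `hubnet` provides tools for studying
how those few outgoing hubs control the global dynamics of binary threshold
networks

```
s(t+1) = sign(W s(t)),    W = T ∘ J,   J_ij ~ N(0, 1) i.i.d.,
```

where `T` is a directed topology drawn from a scale-free-out (SFO),
scale-free-in (SFI) or binomial ensemble. The package is built around the
**lumped-hub approximation**: the `m` largest hubs of a finite
heterogeneous network are merged into one effective hub coupled to a
homogeneous binomial bulk, reducing the topology to three parameters —
bulk mean degree `k_b`, hub strength `σ_h`, and hub sparseness `α` (the
fraction of nodes the hub actually drives). Treating the hub as a feedback
loop around the bulk yields a mean-field damage-spreading theory: the
derivative at the origin of the one-step map of the Hamming distance
between two trajectories,

```
∇d = (2 k_b / π) Σ_{k'≥0} Pois(k'; k_b) [ α·atan(1/√(k'+σ_h²)) + (1−α)·atan(1/√k') ],
```

predicts convergence to a (quasi-)fixed point iff `∇d < 1`, a critical hub
strength `σ_crit(k_b, α)` solving `∇d = 1`, and a **factor-of-half rule**:
restoring the hub as a dynamic node halves the convergence probability.
This explains the striking asymmetry between SFO ensembles (outgoing hubs
act like a chaos-suppressing external drive) and their SFI transposes
(incoming hubs do nothing, convergence dies with network size).

The package implements, with tests at every level:

- ensemble generators (discretized-Pareto SFO, transposed SFI, binomial,
  deterministic fixtures) and Gaussian strength composition;
- a compiled asynchronous threshold simulator with frozen-core detection
  and quasi-fixed-point classification (frozen core ≥ 0.9);
- the lumped-hub reduction at three coarse-graining levels (exact pattern,
  sparse Gaussian, dense Gaussian) with open/closed-loop assembly;
- the mean-field theory (`grad_d`, `sigma_crit`, convergence/flip time
  scales) plus an independent Monte-Carlo damage-spreading oracle;
- exhaustive fixed-point enumeration (Gray-code, `n ≤ 24`), ensemble
  censuses and paired/unpaired Poisson references;
- trajectory statistics (participation ratio, autocorrelation decay) and
  TSV/MatrixMarket round-trip I/O with a config-driven experiment runner
  (`run_experiment()`, plus a thin CLI in `inst/cli/hubnet.R`).

## Worked example

Reduce one scale-free network to its lumped-hub description, ask the
theory whether it converges, and check both answers by simulation:

```r
library(hubnet)

top <- sample_topology(ensemble_params(1500, "sfo", gamma = 2.4, k_min = 1),
                       seed = 7)
top
#> <topology> sfo  n = 1500  edges = 4257  max out-degree = 105

pars <- extract_lumped_params(top, m = 4)
pars
#> <lumped_hub_params> k_b = 2.653  sigma_h = 1.035  alpha = 0.1711  m = 4  k_h = 13

mft_prediction(pars$k_b, pars$sigma_h, pars$alpha, n = 1500, k_h = pars$k_h)
#> # A tibble: 1 × 9
#>     k_b sigma_h alpha grad_d sigma_crit converges_open_loop p_closed_loop ...
#> 1  2.65    1.03 0.171   1.05       2.38 FALSE                           0
```

The extracted hub (`σ_h = 1.03`) is weaker than this realization's critical
strength (`σ_crit = 2.38`), so `∇d = 1.05 > 1`: damage spreads and the
theory predicts no convergence. Simulation and the model-free
damage-spreading oracle agree:

```r
lh <- build_sparse_gaussian(pars, n_bulk = 1496, seed = 8)
run_dynamics(assemble_system(lh, "open"), seed = 9)
#> <dynamics_result> frozen core = 0.6444 -> none

grad_d_oracle(assemble_system(lh, "open"), n_trials = 400, seed = 10)
#> # A tibble: 1 × 3
#>   estimate     se n_trials
#> 1     1.05 0.0520      400
```

The frozen core stalls at 64% — below the 0.9 quasi-fixed-point threshold —
and the Monte-Carlo derivative estimate `1.05 ± 0.05` lands on the analytic
value. For small dense networks the fixed-point structure can be counted
exactly and compared to its paired-Poisson reference (`M/2 ~ Poisson(1/2)`,
mean count 1):

```r
poisson_reference(1/2, paired = TRUE, max_m = 4)
#> # A tibble: 5 × 2
#>       m probability
#> 1     0      0.607
#> 2     1      0
#> 3     2      0.303
#> 4     3      0
#> 5     4      0.0758
```

See `vignette("lumped-hub-methods")` for the model assumptions, parameter
conventions (including the `1/n` weight normalization used by the census
ensemble) and numerical choices.

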
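---
title: "Detecting alternative dynamical attractors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alternative dynamical attractors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dynregime)
```

This vignette is the package's own account of what the regime test computes,
which choices were genuinely open when it was built, and what the shipped
tests do and do not establish.

## The procedure

Given two labelled segments of a time series (the *regimes*), each
standardized to mean 0 and sample sd 1, the test asks whether one segment's
dynamics can be forecast as well from the other segment's reconstructed
attractor as from its own.

1. **Reconstruction.** Each regime's series is delay-embedded at lag 1 into
   E-dimensional vectors `<Y(t), ..., Y(t-(E-1))>`. The embedding dimension is
   selected per regime by one-step leave-one-out simplex forecasting of the
   series from its own library, maximising the Pearson correlation between
   observations and predictions over `E = 1, ..., E_max`.
2. **Forecasting.** The target regime is forecast one step ahead by simplex
   projection from a library: the E+1 nearest library vectors (Euclidean
   distance) contribute their successor observations with weights
   `w_m ∝ exp(-d_m/d_1)`. In multivariate mode the embedding of a predictor
   variable X retrieves the neighbour times and the library's contemporaneous
   response values are averaged instead (cross-mapping, no one-step shift);
   errors are pooled over the response variables.
3. **Testing.** Absolute prediction errors from the within-regime and
   across-regime forecasts give `D = MAPE_across - MAPE_within`. The null
   distribution pools both error sets and reassigns them at random to groups
   of the original sizes; the one-sided p-value is
   `(1 + #{D_perm >= D_obs}) / (1 + B)`. A significant result (default
   `alpha = 0.05`, `B = 1000`) is a detected dynamical difference, as seen
   from the target regime.

The method assumes the regimes are (approximately) stationary within
themselves, sampled at a constant interval, and long enough to populate a
library at the selected E; it makes no parametric assumptions about the
dynamics or the error distribution.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `E_max` | `min(10, floor(n/2) - 1)` | search ceiling for the embedding dimension; 10 is the conventional ceiling in delay-embedding practice and the n/2 cap guarantees the library always holds at least E+2 vectors |
| `n_permutations` | 1000 | permutation count; at alpha = 0.05 equivalent to the "observed difference above the 95th percentile of permuted differences" rule |
| `alpha` | 0.05 | significance level, recorded in every result |
| `self_exclusion` | `TRUE` | exclude library vectors anchored at the predicted time (see below) |
| `rho` (food chain) | — | observation-noise sd as a fraction of each species' deterministic sd; the landscape protocol spans 0.01–0.3 |
| `sigma`, `dt` (harvesting model) | 0.01, 0.01 | noise magnitude (small, so paths stay in their basin rather than flickering) and Euler–Maruyama step |
| `burn_in`, `output_step` | 2000, 1 | food-chain transient discard and output spacing; regime pools for the experiments use burn-in 5000 so the slow period-doubled cycles settle to their limit levels |

## Numerical choices

* **Lag and horizon.** The delay lag is fixed at 1 sample and forecasts are
  one step ahead; multi-step horizons and larger lags are out of scope.
* **Zero-distance neighbours.** The exponential kernel is undefined when the
  nearest distance is 0; the implementation takes its continuity limit: all
  zero-distance neighbours share the weight equally, positive-distance
  neighbours get 0.
* **Ties.** Neighbour ties at the (E+1)-th position are broken by smaller
  library anchor time, and distances are computed with the same direct
  `sum((x - y)^2)` arithmetic as the exhaustive reference in the test suite,
  so exact ties remain exact and results are bit-reproducible. Permuted
  statistics equal to the observed one (common with discrete errors) count as
  `>=`, with a tolerance scaled to the pooled error range so the p-value is
  invariant under rescaling.
* **Embedding-dimension ties.** The smallest E within 1e-9 of the best
  cross-validated skill wins; a 1-ulp difference between candidate dimensions
  is a tie, not a winner.
* **Degenerate inputs.** Constant series cannot be standardized or embedded
  and raise errors naming the offending regime; an all-identical pooled error
  set yields p = 1 with a warning rather than an exception.
* **ODE and SDE integration.** The food chain uses `deSolve`'s lsoda with
  rtol 1e-8 / atol 1e-10 (halving the tolerances moves the sampled
  pre-chaotic trajectories by less than 1e-5, which the suite checks). The
  stochastic model uses Euler–Maruyama with a non-negativity floor at 1e-12 —
  a no-op at the default noise level, but it keeps the state valid for any
  `sigma`. Skeleton equilibria are found by a dense sign-change scan polished
  with `uniroot`, and the fold points by bisection on the positive-root
  count.

## Design decisions that were genuinely open

**Self-exclusion is by anchor time, not by source.** Within-regime forecasts
must exclude the delay vector anchored at the predicted time, otherwise the
zero-distance self-match reproduces the observation and within-regime errors
are trivially zero. The package applies the same rule by *time*: any library
vector anchored at the target vector's own time is excluded, whichever series
it comes from. For real data whose segments occupy disjoint time ranges this
changes nothing. For simulated comparisons in which target and library derive
from the same deterministic trajectory on a shared grid, it removes the
contemporaneous twin from the across-library too, so that under a true null
(two noisy copies of the same regime) the within and across neighbour pools
are exchangeable and the permutation test is calibrated — the same-regime
check in the acceptance suite verifies the rejection rate sits in the
binomial band around alpha. No wider Theiler window is applied.

**Replicates share the deterministic window.** The food-chain skeleton is
deterministic, so the replicate-level stochastic element in the landscape
experiments is the observation-noise draw: every replicate uses the same
window of the sampled trajectory and a fresh noise realization. The
alternative — drawing a random window phase per replicate — makes even
same-regime comparisons detectably different, because the 5-time-unit
sampling stride is incommensurate with the cycle period (≈52 time units), so
two windows of the *same* attractor cover systematically different phase
sets. That is an artifact of finite sampling, not a dynamical difference, and
fixing the window removes it.

**The stochastic equilibrium.** At K = 0.78 the post-transient trajectory is
constant to numerical precision, so an observation-noise sd proportional to
the deterministic sd degenerates to zero, and standardizing "constant plus
nothing" would amplify integration residue instead. The replicate factory
therefore scales the equilibrium regime's noise by the species' equilibrium
value; after standardization the regime is i.i.d. Gaussian fluctuation around
the fixed point for every noise level — which is what a noise-dominated
equilibrium looks like on the standardized scale, and makes the noise level
irrelevant for this regime by construction.

**The harvesting skeleton.** The bistable model is implemented in its
canonical grazing form `x(1 - x/K) - c x²/(1 + x²)`. The sign-flipped
variant with denominator `1 - x²` is singular at x = 1 and possesses no
bistable window at K = 11, so it cannot generate two alternative stable
branches at all; the canonical form yields folds at c ≈ 1.808 and c ≈ 2.844
(recomputed by `scripts/acceptance.R`), bracketing the harvest-rate grid
1.83–2.73 used by the landscape experiment.

**Food-chain initial state.** The chain has a coexisting predator-free
attractor; from states with too small a consumer-to-predator ratio the
predator collapses and the K labels no longer produce their advertised
regimes. The default initial state (R, C, P) = (0.5, 0.3, 0.8) lies in the
coexistence basin for all four reference K values (the suite verifies each
regime's classification).

**Regime classification counts extremum levels.** An "n-point" limit cycle
is identified by the number of distinct local-extremum levels (maxima and
minima jointly) the standardized trajectory visits: the two-point cycle has
one maximum and one minimum level, the four-point cycle two of each. Levels
are clustered with a 0.1-sd gap rule; clusters wider than 0.02 sd, or more
than eight of them, mean the extrema never settle and the series is called
aperiodic.

**Imputation.** Missing values are filled with the smoothed mean of a
maximum-likelihood local-level state-space model (`StructTS` +
`tsSmooth`) — the minimal structural model for the purpose; observed values
are never altered. When a series is split at a breakpoint, imputation is
applied to the whole series first, then the segments are standardized
independently.

## What the synthetic generators emulate — and what they do not

The generators reproduce the study conditions the test was characterised
under: deterministic attractors of a plausible food web observed with
multiplicative-scaled measurement noise at a fixed sampling stride, and
small-noise stochastic fluctuation around alternative stable states. They do
not emulate process noise in the food chain, flickering (basin-switching)
regimes, irregular sampling, observation error with heavy tails, or slow
parameter drift within a segment. Passing the suite therefore shows the test
is calibrated and powerful under these idealised conditions; it does not by
itself establish performance on field data with trends, seasonality, or
mixed noise sources.

## Known limitations

* Detection is asymmetric by design, and for a noise-dominated target regime
  the across-regime forecast error from a strongly bimodal cyclic library
  (the two-point cycle) systematically exceeds the within-regime error of
  shrunk nearest-neighbour averages — so the test can flag a dynamical
  difference even in the direction "cycle library predicts noise target" at
  long series lengths. The corresponding acceptance check documents this cell
  exceeding the one-half bound expected of it, while the four-point-cycle and
  chaotic libraries stay below it.
* Alternative *stochastic* regimes are separable essentially only near the
  fold bifurcations, where critical slowing down gives the fluctuations
  regime-specific autocorrelation structure, and only with long series; the
  mid-window cells of the stochastic landscape sit near the nominal rate.
* The permutation test treats the pooled absolute errors as exchangeable
  units and ignores their serial dependence; with strongly autocorrelated
  errors the effective sample size is smaller than the error count.

## Problem sizes used by the shipped tests

The suite runs at desk scale, chosen as the smallest sizes at which each
property is stable: oracle-equivalence fixtures of length ≤ 30; white-noise
null checks over 200 seeds at n = 60–100; type-I control from 500 replicate
same-regime tests at series length 40; power cells with 50 replicates at
series length 100 and noise 0.01; stochastic-model cells with 50 replicates
at series length 150; food-chain integrations of 3000 post-transient time
units (8000 for classification runs with burn-in 5000).
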
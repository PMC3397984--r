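---
title: "A flashing Brownian-ratchet model of the actomyosin cross-bridge cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A flashing Brownian-ratchet model of the actomyosin cross-bridge cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(myoratchet)
```

## The model

A myosin head interacting with actin is modelled as an overdamped Brownian
particle on a one-dimensional axis along the thin filament. Two ingredients
define it:

1. **The actomyosin landscape `G_a`.** While attached, the head feels a
   periodic, piecewise-linear, multistable potential: within each period of
   `L = 6 d` (`d = 5.5` nm, one actin monomer) there are four binding
   minima spaced `d` apart whose energies descend by the *bias* `deltaG`
   per forward step; each is separated from the next by a barrier of height
   `B` whose maximum sits at a fraction `lambda` of `d` from the departing
   minimum (steep face first). Over the remaining two monomers —
   sterically inaccessible in the actin double helix, so attachment is
   forbidden there — the landscape climbs back up so that it is exactly
   flat on average. A globally flat landscape can do no work by itself:
   all directed motion must come from switching.

2. **The flashing.** The attachment flag `psi` of each head follows a jump
   process. A detached head binds at rate `f1` only while its elastic
   element is stretched forward by `0 < s <= delta_a` *and* it sits over a
   permitted monomer (Brownian search-and-catch); an attached head detaches
   at the 1957 Huxley rate — `g2` for non-positive strain, `g1 * s /
   delta_a` capped at `g1` for positive strain. Each detachment consumes
   one ATP. With these rates the switching violates detailed balance and
   the ensemble shortens; replacing them by Metropolis rates
   (`jump_model = "equilibrium"`) restores detailed balance and, as the
   tests verify, all mean velocities vanish.

The head, the micro-needle of the single-molecule set-up, and the
thick-filament backbone are each overdamped bodies characterized solely by
drag coefficients. Strains are `s_i = x_i - Z - c_i`, with anchors `c_i`
covering one period uniformly (incommensurate filament periodicities);
reported tension is always `sum(elastic_force(s_i))`.

## Parameters

| parameter | default | units | origin |
|---|---|---|---|
| `kBT` | 4.1 | pN nm | room temperature |
| `gamma_head` | 1.9e-7 | pN s/nm | accepted head drag |
| `Gamma_needle` | 1.9e-4 | pN s/nm | needle ~1000x head drag |
| `Gamma_backbone` | N * 100 * gamma | pN s/nm | scale parameter |
| `d` | 5.5 | nm | actin monomer / observed step size |
| `deltaG` | 8.2 (2 kBT) | pN nm | bias, calibrated from step ratios |
| `B` (single-molecule) | 41 (10 kBT) | pN nm | sub-ms transitions (see below) |
| `lambda` (single-molecule) | 0.1 | — | maximum close to the departing minimum |
| `kappa_plus` | 2.8 | pN/nm | modern stretched crossbridge stiffness |
| `kappa_minus` | 0.28 | pN/nm | free parameter; compressed heads buckle |
| `f1` | 6000 | 1/s | ~150 x realistic attachment rate |
| `g1` | 1500 | 1/s | 1957 Huxley 10/s x 150 |
| `g2` | 3000 | 1/s | compressed-head detachment (see below) |
| `delta_a` | 5.5 | nm | search-and-catch window |
| `kappa_trap` | 0.1 (0.03/0.3) | pN/nm | mean (low/high) needle stiffness |
| `kappa_link` | 0.3 | pN/nm | 1971-era crossbridge stiffness (see below) |
| `deltaG_ATP` | 100 | pN nm | ~25 kBT per ATP |

The single-molecule barrier is fixed by a first-passage argument: with
`B = 10 kBT` the quadrature MFPT out of a minimum is ~0.2 ms, consistent
with conformational transitions completing in under a millisecond; much
larger barriers would be too slow, much smaller ones would wash out the
discrete steps.

## Time compression for ensemble work

Millisecond protocols at the single-molecule barrier are unaffordable: the
admissible Euler time step scales as `(lambda d)^2 / (2 D) / 100` and the
dwell time grows like `exp(B/kBT)`. The macroscopic preset therefore

* reduces the barrier until the dwell time is exactly 150 x shorter
  (`calibrate_reduced_barrier()`, root-solving on the MFPT quadrature with
  both escape directions absorbing; the Monte-Carlo engine reproduces the
  ratio within sampling error),
* multiplies all rates by the same nominal factor (the defaults above are
  already the x150 values), and
* widens the asymmetry to `lambda = 0.5`, which relaxes the time-step bound
  about 7-fold. Barrier and asymmetry are free parameters of the time-scale
  compression, so the barrier is recalibrated to the 150x target at
  whatever asymmetry is requested.

Consequences the analysis layer must respect: simulated velocities are
tens of times faster than real muscle (`time_rescale_factor()` converts to
real time), and the length-clamp ramp must also be compressed — the
default ramp is 1 microsecond, i.e. the experimental ~150 microsecond step
divided by the same factor, so that the step stays fast relative to the
fast tension recovery. A 100 microsecond ramp in compressed time would be
quasi-static and erase T1.

## Free-parameter calibration

Three parameters the model treats as free were fixed once, against the
qualitative behaviours that define the model, before the acceptance suite
was written:

* **`g1 = 1500/s`.** With a 10x smaller cap the force-clamp stall sits
  near 0.7-0.8 of the isometric tension instead of 1: long-lived stretched
  heads let the ensemble yield below its isometric load. The value used is
  exactly the 1957 Huxley `g1 = 10/s` scaled by the same 150x compression
  as `f1`, and it restores a force-velocity curve that crosses zero at the
  isometric tension within trial noise.
* **`kappa_link = 0.3 pN/nm`.** With the modern 2.8 pN/nm link, one
  forward step loads the link with ~15 pN — ten times the bias force — so
  every step is immediately yanked back and counted step ratios lose all
  sensitivity to `deltaG`. The softer value is the crossbridge stiffness
  scale of the 1971 tension-transient analysis, which is the provenance of
  the symmetric-link assumption; with it the sweep behaves as expected
  (ratio 1 at zero bias, monotone in `deltaG`, decreasing in load).
* **`g2 = 3000/s`** stays at the baseline value: the fully Huxley-scaled
  ~31000/s collapses the duty ratio and with it the isometric tension.

## Step counting in the single-molecule experiment

The raw trajectory crosses minima far more often than any experiment would
report: after a forward hop the stretched link exceeds the shallow backward
face of the potential and the head is pulled straight back within
microseconds. `simulate_sme()` therefore logs raw crossings (`hops`, which
carry the exact bookkeeping `N_f = N_b + 3` for completed runs) but counts
*steps* with `detect_steps()`: running-median filtering followed by
nearest-level assignment with a hysteresis band, exactly as one would
analyse a measured staircase. Each run starts at the highest minimum and
stops the first time the head reaches a lowest minimum — the attached head
cannot hydrolyse ATP in this reduced set-up, so without the stopping rule
the bias would drive every trajectory into the deep trap and the forward/
backward ratio would decay with simulation length.

`bias_sweep()` repeats terminated runs over a `(deltaG, F)` grid, pools
counts, bootstraps confidence intervals over runs and fits
`ln ratio ~ F` per bias; `estimate_bias_from_sweep()` picks the grid bias
whose fitted curve matches observed ratios. `naive_bias_estimate()`
implements the constant-force inversion `kBT ln(Nf/Nb) + F d`; the tests
verify it *under*estimates the generating bias, which is the point: the
needle's drag is three orders of magnitude above the head's, so the force
on the head varies during a jump.

## Numerical choices

* **Integration** is Euler–Maruyama; `dt` must sit two orders of magnitude
  below both the elastic relaxation time `gamma/kappa_plus` and the
  steep-face diffusion time `(lambda d)^2 / 2D`, and every jump rate obeys
  `r dt <= 0.01` (enforced at run entry and in configuration loading;
  `max_stable_dt()` exposes the bound).
* **Jump scheme** is a per-step Bernoulli flip, not Gillespie: the rates
  depend continuously on the diffusing positions.
* **First-passage sampling** adds a Brownian-bridge crossing test between
  consecutive Euler points (crossing probability
  `exp(-2 (b - x)(b - x') / sigma^2)`), removing the leading
  `O(sqrt(dt))` detection bias; dwell-time runs additionally use a finer
  `dt` (2e-11 s) because the stationary density under the 0.55 nm steep
  face is otherwise under-resolved. The same cusp-resolution argument sets
  the finer step used in the Boltzmann-equilibrium checks.
* **Breakpoint tie-break**: the force at a breakpoint uses the
  forward-side segment — measure zero, but deterministic.
* **Forbidden-span profile**: a single return maximum at
  `(binding_sites + lambda) d`, `B + (binding_sites - 1) deltaG` above the
  lowest minimum; continuous, no spurious local minimum, zero net drop per
  period. The shape of this span is unconstrained by data; any monotone
  climb/descent with the same endpoints would do.
* **Backbone noise is omitted** in the force clamp: its variance is
  suppressed by the backbone drag (>= 1000 x the head drag), and the
  force-velocity relation is unchanged within trial noise; the backbone is
  deterministic given the summed elastic force.
* **Anchors are stratified** (`c_i = (i - 1/2) L / N`) rather than drawn
  uniformly: same uniform coverage, no `O(1/sqrt(N))` sampling artifact.
  Random placement remains available.
* **T1** uses the tangent method: a line fitted over a short early-recovery
  window, extrapolated back to the end of the ramp; windows at or below a
  fifth of the fast time constant keep the extrapolation error near 1%.
* **T2** is the mean over the first post-ramp window whose rolling slope is
  within noise of zero (and whose change is a negligible fraction of the
  transient amplitude) — the plateau between fast recovery and slow creep.
* **Velocity** comes from the first steady trailing window of `Z(t)`:
  either R^2 >= 0.99 (clean shortening) or no significant trend among the
  slopes of six consecutive segments. The second path matters near stall,
  where the backbone is a bounded random walk and R^2 is structurally low
  although the velocity is well defined (and near zero).
* **Efficiency bound**: the event log stores each motor's total energy
  (elastic + `psi * G_a`) immediately before and after every flip. The
  energy the flashing injects is the sum of *positive* jumps of that
  energy — a detachment from a deep minimum raises the motor's energy at
  the expense of ATP — and the bound is mechanical power divided by the
  injection rate. The net-sum variant (signed sum) is also computed and
  reported alongside; the positive-part form is the default and is the one
  that provably dominates the direct efficiency.

## The synthetic-fixture generator

`make_fixture()` produces the deterministic traces the analysis operations
are validated on before they touch simulation output: staircases with known
step times and directions (step detection), single-exponential recoveries
with known elastic level (T1), double-exponential recoveries with a known
intermediate plateau (T2), and linear shortening with known slope
(velocity). Optional Gaussian noise is seeded. These fixtures emulate the
*shape* of experimental traces, not their physics: passing them shows the
extractors are correct, not that the simulator reproduces muscle; that link
is made separately by the property tests (equilibrium statistics,
first-passage oracles, null models, orderings across loads).

## Problem sizes

The shipped tests and the acceptance script use: 64 heads (32 for the
N-invariance check, 16 for null models), isometric settles of 4-5 ms,
clamp phases of 2-2.5 ms with 5 trials per load, 250-2200 first-passage
escapes per barrier, and 10-24 single-molecule runs per sweep point capped
at 4 ms. These sizes put every reported statistic's sampling error well
inside its test tolerance while keeping the full suite in the tens of
minutes on one core; all of them scale up through the public arguments
(`n_trials = 11` reproduces the reporting convention of the ensemble
observables).

## Known limitations

* The geometry is strictly one-dimensional: no actin helix, no lever-arm
  azimuth, no distinction between the two structural scenarios that both
  map onto the same landscape.
* Attachment-detachment chemistry is reduced to the two-state flag with
  one ATP per detachment; there is no weakly-bound state, which is why the
  direct efficiency underestimates and the Sekimoto-type bound brackets
  the plausible range.
* Tendon compliance, activation latency and inter-sarcomere coupling are
  outside the model; simulated rising phases start at force zero with no
  latency.
* The eccentric regime (loads above isometric) is qualitative: velocities
  are non-positive with a plateau-like saturation, but no experimental
  eccentric dataset constrains the parameters here.
* Near stall, velocities are small differences on top of a thermal walk;
  they are meaningful only as means over trials, which is how the
  protocols report them.
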
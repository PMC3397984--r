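# myoratchet

Muscle contracts because myosin heads cyclically attach to actin, pull, and
detach, consuming one ATP per cycle. `myoratchet` simulates this cross-bridge
cycle as a **flashing Brownian ratchet**: each head is an overdamped particle
whose position `x` obeys the Langevin equation

    gamma dx/dt = -psi * dG_a(x)/dx - dE_el(x - z)/dx + sqrt(2 kBT gamma) xi(t)

where `G_a` is a piecewise-linear, multistable actomyosin potential
(periodic, flat on average, with four binding minima per six-monomer period
that descend by a bias `deltaG` per 5.5 nm step), `E_el` is the asymmetric
elastic element connecting the head to the thick-filament backbone at anchor
`z`, and `psi` is a two-state jump process (attached/detached) with
strain-dependent rates — attachment only while thermal fluctuations stretch
the element forward over a permitted monomer (Brownian search-and-catch),
detachment with the classic 1957 Huxley shape. Because the landscape is
globally flat, directed force production exists only while the jump process
breaks detailed balance; switching to equilibrium (Metropolis) rates is
built in as a null model.

The package provides, as tested building blocks:

* **model core** — the potential constructor and evaluators, the asymmetric
  elastic element, the steric attachment region, Boltzmann-density oracles;
* **stochastic engine** — compiled Euler–Maruyama integration with a
  per-step Bernoulli jump process, Brownian-bridge first-passage sampling,
  closed-form and quadrature mean-first-passage-time (MFPT) oracles, and the
  dwell-time calibration that fixes the reduced ("macroscopic") barrier;
* **single-molecule experiment** — a head coupled through a symmetric link
  to a high-drag micro-needle held by a trap; forward/backward step
  counting on filtered staircase traces; the bias-estimation sweep over
  `(deltaG, F)` with exponential fits, and the naive constant-force
  inversion it corrects;
* **half-sarcomere ensemble** — N parallel heads on a rigid backbone with
  isometric, length-clamp and force-clamp protocols (11-trial convention);
* **observables** — T1/T2 tension transients (tangent method,
  plateau detection), force–velocity curves, attachment/strain statistics,
  occupancy of the binding minima, ATP accounting, thermodynamic efficiency
  and its flashing-ratchet upper bound;
* **interface** — YAML configuration with validated cross-field
  constraints, TSV trace I/O with provenance headers, ground-truth fixture
  generation, and a command-line entry point (`exec/myoratchet`).

## Worked example

```r
library(myoratchet)

env <- physical_env()                     # kBT = 4.1 pN nm, gamma = 1.9e-7
sp  <- potential_spec()                   # d = 5.5 nm, deltaG = 2 kBT, B = 10 kBT
pot <- build_potential(sp)
pot$breakpoints
#>       x energy
#> 1  0.00    0.0
#> 2  0.55   41.0
#> 3  5.50   -8.2
#> 4  6.05   32.8
#> 5 11.00  -16.4
#> 6 11.55   24.6
#> 7 16.50  -24.6
#> 8 22.55   41.0
#> 9 33.00    0.0

## sub-millisecond escapes at the single-molecule barrier
tau <- dwell_time_quadrature(env, pot)
round(tau * 1e3, 3)                       # ms
#> [1] 0.197

## reduced barrier for the macroscopic runs: 150x faster dwell
B_macro <- calibrate_reduced_barrier(env, sp, target_ratio = 150)
round(B_macro / env$kBT, 2)               # in kBT
#> [1] 3.12

dw <- mean_dwell_time(env, build_potential(potential_spec(barrier = B_macro)),
                      integrator_spec(dt = 2e-11, seed = 1), n_escapes = 300)
round(tau / dw$mean)                      # measured compression
#> [1] 145

## naive constant-force bias estimate from counted steps
naive_bias_estimate(jump_counts(28, 7), F = 0, d = sp$d, kBT = env$kBT)
#> [1] 5.683807
```

The breakpoint table is one period of the landscape: four minima descending
by 8.2 pN nm (2 kBT) per step, barriers 41 pN nm above their departing
minima with the maximum at 10% of the step (steep face first), and a single
return climb over the two forbidden monomers that restores flatness. The
mean dwell time in a minimum is 0.197 ms — consistent with sub-millisecond
conformational transitions — and reducing the barrier to 3.12 kBT
compresses it about 150-fold (the Monte-Carlo check above gives 145 with
300 escapes), which is what makes millisecond-scale ensemble protocols
computable. The last line shows the constant-force bias inversion: 28
forward versus 7 backward steps at zero load suggests only ~1.4 kBT, an
underestimate of the true 2 kBT bias because the sluggish needle, not a
constant force, loads the head during a jump — quantifying that bias error
is the purpose of `bias_sweep()`.

Ensemble protocols follow the same pattern; see the methods vignette
(`vignettes/cross-bridge-ratchet.Rmd`) for the model details, parameter
table and design choices:

```r
specs <- sarcomere_specs(env, build_potential(macro_potential_spec(env)),
                         elastic_spec(), rate_spec(),
                         integrator_spec(dt = 5e-10, seed = 1))
st  <- init_ensemble(64, potential_period(specs$pot$spec))
iso <- run_isometric(st, specs, duration = 5e-3)       # rising phase -> T0
fc  <- run_force_clamp(iso$state, specs, beta = 0.3, T0 = iso$T0)
extract_velocity(fc$trace)                              # nm/s, shortening > 0
```

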
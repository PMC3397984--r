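# Shared reference objects. All seeds fixed; heavy ensemble simulations are
# computed once per test run and cached for the blocks that share them.

ref_env <- function() physical_env()

ref_spec <- function(...) potential_spec(...)

ref_pot <- function(...) build_potential(potential_spec(...))

# reference single-molecule geometry: d = 5.5 nm, deltaG = 2 kBT,
# B = 10 kBT, lambda = 0.1
REF <- list(d = 5.5, dG = 8.2, B = 41, lam = 0.1, kBT = 4.1,
            gamma = 1.9e-7)

.sim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- compute()
  .sim_cache[[key]]
}

# macroscopic study conditions: reduced barrier at lambda = 0.5,
# Huxley-scaled rates, N = 64
macro_specs <- function(record_stride = 500L) {
  cache_get(paste0("macro_specs_", record_stride), function() {
    env <- physical_env()
    spm <- macro_potential_spec(env)
    sarcomere_specs(env, build_potential(spm), elastic_spec(), rate_spec(),
                    integrator_spec(dt = 5e-10, seed = 1,
                                    record_stride = record_stride))
  })
}

# isometric settle + force clamps over the load grid, 5 trials each;
# shared by the ratchet-physics and thermodynamics acceptance blocks
ensemble_grid <- function() {
  cache_get("ensemble_grid", function() {
    specs <- macro_specs()
    L <- potential_period(specs$pot$spec)
    n_trials <- 5L
    betas <- c(0, 0.3, 0.6, 1, 2.5)
    trials <- vector("list", n_trials)
    for (k in seq_len(n_trials)) {
      st <- init_ensemble(64L, L)
      iso <- run_isometric(st, specs, 5e-3, seed = 4000 + k)
      clamps <- lapply(betas, function(b) {
        run_force_clamp(iso$state, specs, b, iso$T0, duration = 2.5e-3,
                        seed = 5000 + k * 29 + round(b * 10))
      })
      names(clamps) <- paste0("b", betas)
      trials[[k]] <- list(iso = iso, clamps = clamps)
    }
    list(betas = betas, trials = trials)
  })
}

velocity_matrix <- function() {
  eg <- ensemble_grid()
  vapply(eg$trials, function(tr) {
    vapply(tr$clamps, function(cl)
      as.numeric(extract_velocity(cl$trace)), numeric(1))
  }, numeric(length(eg$betas)))
}
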
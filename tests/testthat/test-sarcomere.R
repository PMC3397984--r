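small_specs <- function(seed = 1L, stride = 200L) {
  sarcomere_specs(ref_env(), build_potential(macro_potential_spec(ref_env())),
                  elastic_spec(), rate_spec(),
                  integrator_spec(dt = 5e-10, seed = seed,
                                  record_stride = stride))
}

test_that("ensemble initialization is stratified, detached and tension-free", {
  st <- init_ensemble(4, 33)
  expect_equal(st$motors$c, c(4.125, 12.375, 20.625, 28.875))
  expect_identical(sum(st$motors$psi), 0L)
  expect_identical(ensemble_tension(st, elastic_spec()), 0)
  expect_identical(st$Z, 0)
  expect_error(init_ensemble(0, 33), "N")
  # random placement stays inside one period
  str <- init_ensemble(50, 33, seed = 3, placement = "random")
  expect_true(all(str$motors$c >= 0 & str$motors$c < 33))
})

test_that("with all rates zero no head attaches and no net tension develops", {
  specs <- small_specs()
  specs$rates <- rate_spec(f1 = 0, g1 = 0, g2 = 0)
  st <- init_ensemble(16, potential_period(specs$pot$spec))
  out <- run_isometric(st, specs, 1e-3, seed = 3)
  expect_identical(out$trace$tension_pN[1], 0)      # zero strain at start
  expect_identical(nrow(out$events), 0L)
  expect_identical(sum(out$state$motors$psi), 0L)
  expect_true(all(out$trace$n_attached == 0L))
  # detached springs fluctuate thermally but exert no mean tension
  tn <- out$trace$tension_pN[out$trace$t_s > 2e-4]
  n_eff <- length(tn) / 20       # generous correlation allowance
  expect_lt(abs(mean(tn)), 4 * stats::sd(tn) / sqrt(n_eff))
})

test_that("ensemble runs are reproducible and tension is additive", {
  specs <- small_specs()
  st <- init_ensemble(16, potential_period(specs$pot$spec))
  a <- run_isometric(st, specs, 4e-4, seed = 5)
  b <- run_isometric(st, specs, 4e-4, seed = 5)
  expect_identical(a$trace, b$trace)
  # recorded tension at the final sample equals the sum over the state
  expect_equal(tail(a$trace$tension_pN, 1),
               ensemble_tension(a$state, specs$el))
  # Z stays put under the length clamp mode
  expect_true(all(a$trace$Z_nm == 0))
})

test_that("ATP bookkeeping equals the number of detachment events exactly", {
  specs <- small_specs()
  st <- init_ensemble(32, potential_period(specs$pot$spec))
  out <- run_isometric(st, specs, 1.5e-3, seed = 8)
  n_detach <- sum(out$events$kind == "detach")
  expect_gt(n_detach, 0)
  expect_identical(sum(out$state$motors$atp_used), n_detach)
  expect_identical(tail(out$trace$atp_cum, 1), n_detach)
  # every attachment event happened over a permitted monomer
  att <- out$events[out$events$kind == "attach", ]
  expect_gt(nrow(att), 0)
  expect_true(all(attachment_allowed(specs$pot$spec, att$x_nm)))
})

test_that("isometric tension rises to a plateau", {
  specs <- small_specs()
  st <- init_ensemble(64, potential_period(specs$pot$spec))
  out <- run_isometric(st, specs, 4e-3, seed = 21)
  tr <- out$trace
  third <- cut(tr$t_s, breaks = 3, labels = FALSE)
  m <- tapply(tr$tension_pN, third, mean)
  expect_gt(m[2], m[1])           # rising
  expect_gt(out$T0, 0)
  # plateau: last two thirds statistically level (slope consistent with 0
  # relative to the rise)
  expect_lt(abs(m[3] - m[2]), 0.5 * (m[2] - m[1]) + 0.2 * out$T0)
})

test_that("length steps shift tension by the frozen elastic prediction", {
  specs <- small_specs(stride = 100L)
  st <- init_ensemble(64, potential_period(specs$pot$spec))
  iso <- run_isometric(st, specs, 3e-3, seed = 13)
  delta <- -2
  lc <- run_length_clamp(iso$state, specs, delta, t_step = 1e-4,
                         duration = 4e-4, freeze_heads = TRUE, seed = 14)
  s <- iso$state$motors$x - iso$state$Z - iso$state$motors$c
  pred <- sum(elastic_force(specs$el, s + delta))
  expect_equal(extract_t1(lc, window = 1e-5), pred, tolerance = 0.02)
  # the release really dropped the tension
  expect_lt(pred, ensemble_tension(iso$state, specs$el))
})

test_that("protocol runner replicates trials deterministically with summaries", {
  specs <- small_specs()
  pr <- protocol_spec("isometric", duration = 6e-4, n_trials = 2L)
  res1 <- run_protocol(specs, pr, master_seed = 3, N = 12L, settle = 6e-4)
  res2 <- run_protocol(specs, pr, master_seed = 3, N = 12L, settle = 6e-4)
  expect_identical(res1$trials[[1]]$trace, res2$trials[[1]]$trace)
  expect_identical(nrow(res1$summary), 2L)
  expect_true(all(is.finite(attr(res1$summary, "sd"))))
  one <- run_protocol(specs, pr <- protocol_spec("isometric",
                                                 duration = 4e-4,
                                                 n_trials = 1L),
                      master_seed = 1, N = 8L, settle = 4e-4)
  expect_length(one$trials, 1L)
  expect_error(run_force_clamp(init_ensemble(4, 33), specs, beta = 3, T0 = 10),
               "beta")
})

test_that("normalized attachment is unchanged when N doubles", {
  specs <- small_specs()
  frac <- function(N, seeds) {
    vapply(seeds, function(s) {
      st <- init_ensemble(N, potential_period(specs$pot$spec))
      out <- run_isometric(st, specs, 2.5e-3, seed = s)
      tr <- out$trace
      mean(tr$n_attached[tr$t_s >= 1.5e-3]) / N
    }, numeric(1))
  }
  f32 <- frac(32L, 301:303)
  f64 <- frac(64L, 304:306)
  se <- sqrt(stats::sd(f32)^2 / 3 + stats::sd(f64)^2 / 3)
  expect_lt(abs(mean(f32) - mean(f64)), 3 * se + 0.02)
})
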
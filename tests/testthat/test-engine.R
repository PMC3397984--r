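test_that("langevin step reduces to drift and diffusion limits", {
  env <- ref_env()
  dt <- 1e-9
  expect_identical(langevin_step(2, 0, env, dt, 0), 2)
  # deterministic drift
  expect_equal(langevin_step(0, 10, env, dt, 0), 10 * dt / env$gamma_head)
  # free diffusion: ensemble MSD = 2 D t within 3 standard errors
  set.seed(42)
  n <- 1e4
  x <- numeric(n)
  steps <- 50L
  for (k in seq_len(steps)) x <- langevin_step(x, 0, env, dt, stats::rnorm(n))
  t <- steps * dt
  msd <- mean(x^2)
  se <- stats::sd(x^2) / sqrt(n)
  D <- diffusion_coefficient(env)
  expect_lt(abs(msd - 2 * D * t), 3 * se)
})

test_that("attachment follows the Brownian search-and-catch rule", {
  rs <- rate_spec(f1 = 6000, attach_window = 5.5, rate_scale = 2)
  sp <- ref_spec()
  expect_identical(attach_rate(rs, -1, 2 * REF$d, sp), 0)
  expect_identical(attach_rate(rs, 2.75, 2 * REF$d, sp), 12000)
  # forbidden monomer blocks attachment even at favourable strain
  expect_identical(attach_rate(rs, 2.75, 5 * REF$d, sp), 0)
  expect_identical(attach_rate(rs, 5.6, 2 * REF$d, sp), 0)  # beyond window
})

test_that("detachment has the capped Huxley shape", {
  rs <- rate_spec(g1 = 1500, g2 = 3000, attach_window = 5.5)
  expect_identical(detach_rate(rs, -0.5), 3000)
  expect_equal(detach_rate(rs, 1e-9), 1500 * 1e-9 / 5.5)  # continuous at 0+
  expect_identical(detach_rate(rs, 5.5), 1500)
  expect_identical(detach_rate(rs, 50), 1500)              # capped
  expect_equal(detach_rate(rs, 2.75), 750)
})

test_that("jump update flips states, counts ATP and records energies", {
  pot <- ref_pot()
  el <- elastic_spec()
  st <- motor_state(x = REF$d, psi = 1L)
  # zero rate: nothing happens
  r0 <- jump_update(st, c(attach = 0, detach = 0), 1e-6, 0.5)
  expect_identical(r0$state, st)
  expect_null(r0$event)
  # certain detach: ATP incremented, energies elastic +/- potential
  r1 <- jump_update(st, c(attach = 0, detach = 1e4), 1e-6, 0.001,
                    pot = pot, el = el, z = REF$d - 2, t = 1)
  expect_identical(r1$state$psi, 0L)
  expect_identical(r1$state$atp_used, 1L)
  expect_equal(r1$event$E_before, elastic_energy(el, 2) - REF$dG)
  expect_equal(r1$event$E_after, elastic_energy(el, 2))
  # rate*dt guard
  expect_error(jump_update(st, c(attach = 0, detach = 1e6), 1e-6, 0.5),
               "rate \\* dt")
  # Bernoulli statistics: flip fraction = r dt within 3 binomial SE
  set.seed(7)
  n <- 1e5
  p <- 0.005  # rate 5e3 * dt 1e-6
  det <- motor_state(psi = 0L)
  got <- 0L
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    if (!is.null(jump_update(det, c(attach = 5e3, detach = 0), 1e-6,
                             u[i])$event)) {
      got <- got + 1L
    }
  }
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(got - n * p), 3 * se)
})

test_that("closed-form MFPT has the right limits and matches quadrature", {
  env <- ref_env()
  D <- diffusion_coefficient(env)
  ell <- 0.55
  # diffusive limit
  expect_equal(mfpt_closed_form(ell, 0, D, env$kBT), ell^2 / (2 * D))
  expect_equal(mfpt_closed_form(ell, 1e-12, D, env$kBT), ell^2 / (2 * D),
               tolerance = 1e-6)
  # strictly increasing in opposing force
  f <- seq(0, 100, by = 10)
  taus <- mfpt_closed_form(ell, f, D, env$kBT)
  expect_true(all(diff(taus) > 0))
  # reference climb: against the quadrature oracle within 0.1%
  Fref <- REF$B / (REF$lam * REF$d)
  t_cf <- mfpt_closed_form(ell, Fref, D, env$kBT)
  t_q <- mfpt_quadrature(function(x) Fref * x, 0, ell, 0, D, env$kBT,
                         boundary = "reflecting_lower")
  expect_equal(t_q, t_cf, tolerance = 1e-3)
})

test_that("quadrature MFPT solves the flat double-absorbing case exactly", {
  env <- ref_env()
  D <- diffusion_coefficient(env)
  a <- 0; b <- 11; x0 <- 5.5
  tau <- mfpt_quadrature(function(x) 0 * x, a, b, x0, D, env$kBT,
                         boundary = "both_absorbing")
  expect_equal(tau, (x0 - a) * (b - x0) / (2 * D), tolerance = 1e-6)
})

test_that("single-motor runs are reproducible and respect trivial limits", {
  env <- ref_env()
  pot <- ref_pot()
  it <- integrator_spec(dt = 6e-11, seed = 99, record_stride = 100L)
  r1 <- simulate_motor(env, pot, NULL, NULL, it, duration = 2e-6, x0 = REF$d)
  r2 <- simulate_motor(env, pot, NULL, NULL, it, duration = 2e-6, x0 = REF$d)
  expect_identical(r1$trace, r2$trace)
  # zero duration: only the initial sample
  r0 <- simulate_motor(env, pot, NULL, NULL, it, duration = 0, x0 = 1)
  expect_identical(nrow(r0$trace), 1L)
  expect_identical(r0$trace$x_nm, 1)
  # oversized dt is rejected with the stability bound
  bad <- integrator_spec(dt = 1e-8, seed = 1)
  expect_error(simulate_motor(env, pot, NULL, NULL, bad, 1e-6), "bound")
})

test_that("attached motor with jumps off equilibrates to the Boltzmann density", {
  env <- ref_env()
  # deep single-molecule well (escapes negligible over the run)
  pot <- ref_pot(barrier = 15 * env$kBT)
  # fine dt: the stationary density has a cusp at the minimum which the
  # Euler scheme smears over one noise step
  it <- integrator_spec(dt = 1.5e-11, seed = 31, record_stride = 800L)
  r <- simulate_motor(env, pot, NULL, NULL, it, duration = 1.3e-3,
                      x0 = REF$d, psi0 = 1L)
  x <- r$trace$x_nm
  lam <- REF$lam; d <- REF$d
  dom <- c(lam * d, (1 + lam) * d)   # well 1 between its flanking maxima
  x <- x[x > dom[1] & x < dom[2]]
  expect_gt(length(x), 5e4)
  cdf <- boltzmann_cdf(pot, env$kBT, dom)
  ks <- suppressWarnings(stats::ks.test(x, cdf))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("flashing with detailed-balance rates produces no net drift", {
  env <- ref_env()
  pot <- ref_pot(deltaG = 0, barrier = 2 * env$kBT, asymmetry_lambda = 0.5)
  rs <- rate_spec(f1 = 5000, g1 = 0, g2 = 0)
  disp <- vapply(1:10, function(k) {
    it <- integrator_spec(dt = 5e-10, seed = 600 + k, record_stride = 1000L)
    r <- simulate_motor(env, pot, NULL, rs, it, duration = 3e-4, x0 = 0,
                        psi0 = 1L, jump_model = "equilibrium")
    tail(r$trace$x_nm, 1)
  }, numeric(1))
  se <- stats::sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp)), 3 * se)
})

test_that("Monte-Carlo dwell times scale with drag and match the oracle", {
  env <- ref_env()
  spm <- macro_potential_spec(env)   # reduced barrier: cheap escapes
  pot <- build_potential(spm)
  q <- dwell_time_quadrature(env, pot)
  it <- integrator_spec(dt = 5e-10, seed = 17)
  dw <- mean_dwell_time(env, pot, it, 600)
  expect_gt(dw$mean, 0)
  expect_lt(abs(dw$mean - q) / q, 3 * dw$stderr / q + 0.02)
  # doubling gamma doubles the mean dwell time
  env2 <- physical_env(gamma_head = 2 * env$gamma_head)
  dw2 <- mean_dwell_time(env2, pot, it, 600)
  se <- sqrt((2 * dw$stderr)^2 + dw2$stderr^2)
  expect_lt(abs(dw2$mean - 2 * dw$mean), 3 * se + 0.04 * dw2$mean)
  expect_error(mean_dwell_time(env, pot, it, 10), "30")
})

test_that("barrier calibration is monotone and exact at ratio one", {
  env <- ref_env()
  sp <- ref_spec()
  expect_identical(calibrate_reduced_barrier(env, sp, 1), sp$barrier)
  B50 <- calibrate_reduced_barrier(env, sp, 50)
  B150 <- calibrate_reduced_barrier(env, sp, 150)
  expect_lt(B150, B50)
  expect_lt(B50, sp$barrier)
  expect_gt(B150, sp$deltaG)
  # achieved quadrature ratio within 1%
  tau_ref <- dwell_time_quadrature(env, build_potential(sp))
  tau_m <- dwell_time_quadrature(env, build_potential(ref_spec(barrier = B150)))
  expect_equal(tau_ref / tau_m, 150, tolerance = 0.01)
  expect_error(calibrate_reduced_barrier(env, sp, 1e9), "ratio")
})
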
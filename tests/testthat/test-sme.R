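test_that("step detection recovers staircase ground truth", {
  d <- REF$d
  mk <- function(dirs, sd = 0) {
    make_fixture(fixture_spec("staircase", directions = dirs, step_size = d,
                              level_duration = 2e-3, noise_sd = sd,
                              seed = 2, dt = 2e-5))
  }
  # constant trace: no steps
  cst <- data.frame(t_s = seq(0, 1e-2, by = 1e-4), x_nm = 3.2)
  r0 <- detect_steps(cst, d)
  expect_identical(r0$counts$n_forward, 0L)
  expect_identical(r0$counts$n_backward, 0L)
  # clean staircases
  fw <- detect_steps(mk(c(1, 1, 1))$trace, d)
  expect_identical(fw$counts$n_forward, 3L)
  expect_identical(fw$counts$n_backward, 0L)
  mixed <- detect_steps(mk(c(1, 1, -1))$trace, d)
  expect_identical(mixed$counts$n_forward, 2L)
  expect_identical(mixed$counts$n_backward, 1L)
  # moderate noise does not change the counts (hysteresis + median filter)
  noisy <- detect_steps(mk(c(1, 1, -1), sd = 0.8)$trace, d)
  expect_identical(noisy$counts$n_forward, 2L)
  expect_identical(noisy$counts$n_backward, 1L)
  expect_error(detect_steps(cst, -1), "`d`")
})

test_that("jump ratio pools runs and bootstraps a CI", {
  expect_equal(jump_ratio(jump_counts(70, 10))$ratio, 7)
  runs <- data.frame(n_forward = c(10, 12, 8, 14), n_backward = c(2, 3, 1, 2))
  jr <- jump_ratio(runs, seed = 4)
  expect_equal(jr$ratio, 44 / 8)
  expect_lt(jr$ci[1], jr$ratio)
  expect_gt(jr$ci[2], jr$ratio)
  expect_identical(jr$n_runs, 4L)
  expect_error(jump_ratio(jump_counts(0, 0)), "no jumps")
  # no backward jumps: infinite point estimate, finite lower bound
  jr_inf <- jump_ratio(data.frame(n_forward = c(5, 6), n_backward = c(0, 0)),
                       seed = 4)
  expect_identical(jr_inf$ratio, Inf)
  expect_true(is.finite(jr_inf$ci[1]))
})

test_that("naive constant-force bias inversion", {
  kBT <- REF$kBT; d <- REF$d
  expect_equal(naive_bias_estimate(jump_counts(25, 25), 0, d, kBT), 0)
  expect_equal(naive_bias_estimate(jump_counts(round(exp(2) * 100), 100),
                                   0, d, kBT), 2 * kBT, tolerance = 1e-3)
  expect_equal(naive_bias_estimate(jump_counts(50, 50), 8.2 / d, d, kBT), 8.2)
  expect_error(naive_bias_estimate(jump_counts(5, 0), 0, d, kBT), "positive")
})

test_that("completed single-molecule runs terminate at a lowest minimum", {
  env <- ref_env()
  pot <- ref_pot()
  nd <- needle_spec()
  d <- REF$d; L <- pot$period
  done <- 0L
  for (k in 1:4) {
    it <- integrator_spec(dt = 6e-11, seed = 700 + k, record_stride = 2000L)
    r <- simulate_sme(env, pot, nd, it, max_duration = 7e-3)
    if (r$completed) {
      done <- done + 1L
      x_end <- tail(r$trace$x_nm, 1)
      r_end <- x_end - L * floor(x_end / L)
      expect_lt(abs(r_end - 3 * d), d / 4 + 1e-9)
      # raw crossing bookkeeping: net progress is 3 steps forward (or one
      # step backward into the previous period's lowest minimum)
      nf <- sum(r$hops$direction > 0)
      nb <- sum(r$hops$direction < 0)
      expect_true((nf - nb) %in% c(3L, -1L))
      expect_lte(nf, 3L + nb)
    }
  }
  expect_gt(done, 0L)
})

test_that("single-molecule runs are seed-reproducible", {
  env <- ref_env()
  pot <- ref_pot()
  it <- integrator_spec(dt = 6e-11, seed = 41, record_stride = 2000L)
  r1 <- simulate_sme(env, pot, needle_spec(), it, max_duration = 1e-3)
  r2 <- simulate_sme(env, pot, needle_spec(), it, max_duration = 1e-3)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$counts, r2$counts)
})

test_that("with a frozen needle the head equilibrates in the combined landscape", {
  env <- physical_env(Gamma_needle = 1e7 * 1.9e-7)  # effectively immobile
  pot <- ref_pot()
  nd <- needle_spec(Gamma_needle = env$Gamma_needle, kappa_link = 2.8,
                    kappa_trap = 0.1, X0 = 0)
  it <- integrator_spec(dt = 1.5e-11, seed = 55, record_stride = 800L)
  r <- simulate_sme(env, pot, nd, it, max_duration = 1.3e-3, x0 = 0)
  expect_false(r$completed)   # the stiff spring forbids reaching 3d
  x <- r$trace$x_nm
  combined <- function(y) potential_energy(pot, y) + 0.5 * 2.8 * y^2
  dom <- range(x) + c(-0.2, 0.2)
  grid <- seq(dom[1], dom[2], length.out = 4097)
  w <- exp(-(combined(grid) - min(combined(grid))) / env$kBT)
  cdf_grid <- cumsum(c(0, diff(grid) * (head(w, -1) + tail(w, -1)) / 2))
  cdf <- stats::approxfun(grid, cdf_grid / max(cdf_grid), yleft = 0,
                          yright = 1)
  ks <- suppressWarnings(stats::ks.test(x, cdf))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("sweep tables are deterministic and carry the declared schema", {
  env <- ref_env()
  it <- integrator_spec(dt = 6e-11, seed = 9, record_stride = 2000L)
  sw1 <- bias_sweep(env, ref_spec(), deltaG_grid = 8.2, F_grid = 0,
                    needle = needle_spec(), integ = it, n_runs = 3,
                    max_duration = 3e-3)
  sw2 <- bias_sweep(env, ref_spec(), deltaG_grid = 8.2, F_grid = 0,
                    needle = needle_spec(), integ = it, n_runs = 3,
                    max_duration = 3e-3)
  expect_identical(sw1$Nf, sw2$Nf)
  expect_identical(sw1$Nb, sw2$Nb)
  expect_true(all(c("deltaG_pNnm", "F_pN", "n_runs", "Nf", "Nb", "ratio",
                    "ci_lo", "ci_hi", "fit_slope", "fit_intercept") %in%
                    names(sw1)))
  expect_identical(attr(sw1, "runs")$n_forward, attr(sw2, "runs")$n_forward)
})
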
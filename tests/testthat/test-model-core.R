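test_that("reference potential reproduces an independently built breakpoint table", {
  pot <- ref_pot()
  d <- REF$d; dG <- REF$dG; B <- REF$B; lam <- REF$lam
  # hand-built table: minima at k*d descending by dG, maxima at (k+lam)*d
  # at B above the departing minimum, return maximum at (4+lam)*d with
  # energy B (so that the period closes at zero), back to 0 at 6d
  manual <- data.frame(
    x = c(0, lam * d, d, (1 + lam) * d, 2 * d, (2 + lam) * d, 3 * d,
          (4 + lam) * d, 6 * d),
    energy = c(0, B, -dG, B - dG, -2 * dG, B - 2 * dG, -3 * dG, B, 0))
  expect_equal(pot$breakpoints$x, manual$x)
  expect_equal(pot$breakpoints$energy, manual$energy)
  expect_equal(pot$period, 6 * d)

  # gauge and bias by construction
  expect_identical(potential_energy(pot, 0), 0)
  expect_equal(potential_energy(pot, 3 * d), -24.6)
  expect_equal(potential_energy(pot, lam * d), B)
})

test_that("potential is periodic and flat on average", {
  pot <- ref_pot()
  set.seed(11)
  x <- stats::runif(1000, -100, 100)
  expect_equal(potential_energy(pot, x + pot$period), potential_energy(pot, x),
               tolerance = 1e-12)
  # zero mean slope: energies at period boundaries equal
  expect_equal(potential_energy(pot, 0), potential_energy(pot, pot$period))
  # integral of -force over one period vanishes (piecewise constant force)
  xs <- seq(0, pot$period, length.out = 60001)
  f <- potential_force(pot, xs)
  expect_lt(abs(mean(-f[-length(f)])) * pot$period, 0.15)
})

test_that("potential force follows the segment slopes with forward tie-break", {
  pot <- ref_pot()
  d <- REF$d; dG <- REF$dG; B <- REF$B; lam <- REF$lam
  # climbing face between a minimum and its maximum
  expect_equal(potential_force(pot, 0.2), -B / (lam * d))
  # descending face from the maximum into the next (lower) minimum drops
  # B + dG over (1 - lam) d
  expect_equal(potential_force(pot, 3), (B + dG) / ((1 - lam) * d))
  # at a breakpoint the forward-side segment wins
  expect_equal(potential_force(pot, lam * d), (B + dG) / ((1 - lam) * d))
  expect_equal(potential_force(pot, 0), -B / (lam * d))
})

test_that("attachment region covers exactly the binding run", {
  sp <- ref_spec()
  d <- REF$d; L <- potential_period(sp)
  expect_true(attachment_allowed(sp, 2 * d))
  expect_false(attachment_allowed(sp, 5 * d))
  expect_false(attachment_allowed(sp, 4 * d + L))
  expect_true(attachment_allowed(sp, 0))
  expect_false(attachment_allowed(sp, 4 * d))
  expect_true(attachment_allowed(sp, 4 * d - 1e-9))
  # exactly binding_sites minima lie in the permitted region
  pot <- build_potential(sp)
  bp <- pot$breakpoints
  interior <- bp$x[c(FALSE, diff(sign(diff(bp$energy))) > 0, FALSE)]
  minima <- c(0, interior)  # gauge minimum at the period boundary
  expect_length(minima, sp$binding_sites)
  expect_true(all(attachment_allowed(sp, minima)))
})

test_that("mirrored orientation flips the maximum position", {
  pot_m <- ref_pot(forward_sign = -1)
  lam <- REF$lam; d <- REF$d
  expect_equal(potential_energy(pot_m, (1 - lam) * d), REF$B)
  expect_lt(potential_energy(pot_m, lam * d), REF$B)
})

test_that("asymmetric elastic element is piecewise linear and continuous", {
  el <- elastic_spec(kappa_plus = 2.8, kappa_minus = 0.28)
  expect_identical(elastic_force(el, 0), 0)
  expect_equal(elastic_force(el, 2), 5.6)
  expect_equal(elastic_force(el, -2), -0.56)
  # continuity at zero strain
  expect_equal(elastic_force(el, 1e-12), 0, tolerance = 1e-10)
  expect_equal(elastic_force(el, -1e-12), 0, tolerance = 1e-10)
  # odd only when symmetric
  sym <- elastic_spec(kappa_plus = 2, kappa_minus = 2)
  s <- seq(-3, 3, by = 0.5)
  expect_equal(elastic_force(sym, -s), -elastic_force(sym, s))
  expect_false(isTRUE(all.equal(elastic_force(el, -2), -elastic_force(el, 2))))
  expect_equal(elastic_energy(el, 2), 0.5 * 2.8 * 4)
})

test_that("boltzmann density is normalized and reproduces the bias ratio", {
  env <- ref_env()
  pot <- ref_pot()
  dens <- boltzmann_density(pot, env$kBT, c(0, pot$period), n = 3301L)
  dx <- diff(dens$x)
  expect_equal(sum(dx * (head(dens$density, -1) + tail(dens$density, -1)) / 2),
               1, tolerance = 1e-9)
  # adjacent minima differ by deltaG = 2 kBT: density ratio e^2
  at <- function(x) dens$density[which.min(abs(dens$x - x))]
  expect_equal(at(REF$d) / at(0), exp(2), tolerance = 1e-3)
  # flat potential: uniform density
  flat <- build_potential(potential_spec(deltaG = 0, barrier = 1e-9))
  fd <- boltzmann_density(flat, env$kBT, c(0, 33))
  expect_lt(diff(range(fd$density)) / mean(fd$density), 1e-9)
})

test_that("spec validation names the offending field", {
  expect_error(potential_spec(barrier = 5, deltaG = 8.2), "barrier")
  expect_error(potential_spec(asymmetry_lambda = 1.2), "asymmetry_lambda")
  expect_error(potential_spec(binding_sites = 6), "binding_sites")
  expect_error(elastic_spec(kappa_plus = -1), "kappa_plus")
  expect_error(elastic_spec(kappa_minus = 5, kappa_plus = 2), "kappa_minus")
  expect_error(physical_env(Gamma_needle = 1e-6), "Gamma_needle")
  expect_error(rate_spec(g2 = 10, g1 = 100), "g2")
  expect_error(needle_spec(kappa_trap = 0), "kappa_trap")
})
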
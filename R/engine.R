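#' One Euler-Maruyama step of the overdamped Langevin equation
#'
#' `x' = x + (F/gamma) dt + sqrt(2 kBT dt / gamma) * noise`, the elementary
#' update used by every diffusing body in the model (head, needle). The
#' compiled engines implement exactly this rule; the R-level function exists
#' for unit testing and for building small vectorized experiments such as
#' free-diffusion checks.
#'
#' @param x Position(s), nm.
#' @param total_force Total force on the particle(s), pN (elastic +
#'   `psi` x potential + external).
#' @param env A [physical_env()]; `gamma_head` is the drag used.
#' @param dt Time step, s.
#' @param noise Standard normal draw(s).
#' @return Updated position(s), nm.
#' @export
langevin_step <- function(x, total_force, env, dt, noise) {
  x + total_force * dt / env$gamma_head +
    sqrt(2 * env$kBT * dt / env$gamma_head) * noise
}

#' Attachment rate of a detached head
#'
#' Brownian search-and-catch: the full rate `f1 * rate_scale` applies only
#' while the elastic element is stretched forward by at most
#' `attach_window` and the head sits over a permitted monomer; otherwise 0.
#'
#' @param rs A [rate_spec()].
#' @param strain Elastic strain `s = x - z`, nm.
#' @param x Head position, nm.
#' @param spec A [potential_spec()] (for the steric region).
#' @return Rate in 1/s (vectorized over `strain`/`x`).
#' @export
attach_rate <- function(rs, strain, x, spec) {
  ifelse(strain > 0 & strain <= rs$attach_window & attachment_allowed(spec, x),
         rs$f1 * rs$rate_scale, 0)
}

#' Detachment rate of an attached head
#'
#' Huxley-1957 shape adapted to the landscape geometry: a large constant
#' rate `g2` for non-positive strain (ADP release is easy on a compressed
#' head) and a rate rising linearly with positive strain, capped at `g1`.
#'
#' @param rs A [rate_spec()].
#' @param strain Elastic strain, nm.
#' @return Rate in 1/s (vectorized).
#' @export
detach_rate <- function(rs, strain) {
  ifelse(strain <= 0, rs$g2 * rs$rate_scale,
         rs$g1 * rs$rate_scale * pmin(strain / rs$attach_window, 1))
}

#' One Bernoulli update of the jump process
#'
#' Flips the attachment flag with probability `rate * dt` for the applicable
#' transition; the head position is continuous across the flip (the
#' potential flashes, the particle does not move). A detachment increments
#' the ATP counter by one. The returned event carries the total motor energy
#' (elastic + psi x potential) immediately before and after the flip, the
#' bookkeeping that feeds the efficiency bound.
#'
#' @param state A [motor_state()].
#' @param rates Named numeric `c(attach = , detach = )`, 1/s.
#' @param dt Time step, s; `rate * dt` must not exceed 0.01.
#' @param u Uniform(0,1) draw.
#' @param pot A [build_potential()] result (for event energies); optional
#'   when rates are zero.
#' @param el An [elastic_spec()] or `NULL`.
#' @param z Anchor position, nm.
#' @param t Event timestamp, s.
#' @return A list `(state = updated motor_state, event = jump event or NULL)`.
#' @export
jump_update <- function(state, rates, dt, u, pot = NULL, el = NULL, z = 0,
                        t = 0) {
  rate <- if (state$psi == 1L) rates[["detach"]] else rates[["attach"]]
  if (rate * dt > 0.01) {
    stop("jump_update: rate * dt = ", format(rate * dt),
         " exceeds 0.01; reduce `integrator.dt`", call. = FALSE)
  }
  if (rate <= 0 || u >= rate * dt) {
    return(list(state = state, event = NULL))
  }
  s <- state$x - z
  Eel <- if (is.null(el)) 0 else elastic_energy(el, s)
  U <- if (is.null(pot)) 0 else potential_energy(pot, state$x)
  if (state$psi == 1L) {
    new_state <- motor_state(state$x, 0L, state$c, state$atp_used + 1L)
    event <- list(t = t, kind = "detach", x_at_event = state$x,
                  E_before = Eel + U, E_after = Eel)
  } else {
    new_state <- motor_state(state$x, 1L, state$c, state$atp_used)
    event <- list(t = t, kind = "attach", x_at_event = state$x,
                  E_before = Eel, E_after = Eel + U)
  }
  list(state = new_state, event = event)
}

events_df <- function(ev) {
  data.frame(t_s = ev$t_s, motor = ev$motor,
             kind = c("attach", "detach")[ev$kind],
             x_nm = ev$x_nm, E_before = ev$E_before, E_after = ev$E_after)
}

#' Simulate a single myosin head
#'
#' Full engine for one head: overdamped diffusion in the (flashing)
#' potential, the asymmetric elastic element anchored at a fixed point, and
#' optionally the attach/detach jump process. Runs on the compiled core and
#' is bit-reproducible from the integrator seed.
#'
#' @param env A [physical_env()].
#' @param pot A [build_potential()] result.
#' @param el An [elastic_spec()], or `NULL` for a free head (no elastic
#'   element).
#' @param rates A [rate_spec()], or `NULL` to switch the jump process off
#'   (the attachment flag then stays at its initial value).
#' @param integ An [integrator_spec()].
#' @param duration Simulated time, s.
#' @param external_force Constant external force on the head, pN
#'   (default 0).
#' @param x0,psi0 Initial head position (nm) and attachment flag.
#' @param anchor Anchor position `z` of the elastic element, nm.
#' @param jump_model `"huxley"` (default when `rates` given) for the
#'   search-and-catch/Huxley rates; `"equilibrium"` for detailed-balance
#'   Metropolis rates with attempt frequency `f1` (a null model in which no
#'   net motion can arise); `"none"`.
#' @return A list with `trace` (data.frame `t_s`, `x_nm`, `psi`,
#'   `tension_pN`), `events` (jump event log), and `final` state.
#' @export
simulate_motor <- function(env, pot, el, rates, integ, duration,
                           external_force = 0, x0 = 0, psi0 = 1L,
                           anchor = 0,
                           jump_model = c("huxley", "equilibrium", "none")) {
  jump_model <- match.arg(jump_model)
  if (is.null(rates)) jump_model <- "none"
  jm <- switch(jump_model, none = 0L, huxley = 1L, equilibrium = 2L)
  check_dt(integ, env, pot$spec, el, if (jm != 0L) rates else NULL)
  kp <- if (is.null(el)) 0 else el$kappa_plus
  km <- if (is.null(el)) 0 else el$kappa_minus
  rs <- if (is.null(rates)) rate_spec() else rates
  sp <- pot$spec
  n_steps <- floor(duration / integ$dt)
  res <- cpp_simulate_ensemble(
    bx = pot$breakpoints$x, be = pot$breakpoints$energy, L = pot$period,
    allowed_end = sp$binding_sites * sp$d, d_spacing = sp$d,
    n_bind = sp$binding_sites,
    kp = kp, km = km,
    f1 = rs$f1, g1 = rs$g1, g2 = rs$g2, rate_scale = rs$rate_scale,
    attach_window = rs$attach_window,
    gamma_head = env$gamma_head, kBT = env$kBT, Gb = env$Gamma_backbone,
    dt = integ$dt, n_steps_d = n_steps, stride = integ$record_stride,
    mode = 0L, F_load = 0, ramp_t0 = 0, ramp_dur = 0, ramp_dZ = 0,
    jump_model = jm, freeze_heads = FALSE, Fext_head = external_force,
    Z0 = 0, x_init = x0, psi_init = as.integer(psi0), c_off = anchor,
    atp_init = 0L, seed = integ$seed, record_x = TRUE)
  trace <- data.frame(t_s = res$trace$t_s, x_nm = res$trace$x[, 1],
                      psi = res$trace$psi[, 1],
                      tension_pN = res$trace$tension_pN)
  list(trace = trace, events = events_df(res$events),
       final = motor_state(res$x_final[1], res$psi_final[1], anchor,
                           res$atp_final[1]))
}

#' Closed-form mean first-passage time against a constant force
#'
#' Exact MFPT of an overdamped particle that starts at a reflecting boundary
#' and must travel a distance `ell` against a constant opposing force `F`:
#' with `u = F ell / kBT`,
#' `tau = (ell^2 / D) (e^u - u - 1) / u^2`,
#' reducing to the free-diffusion value `ell^2 / (2 D)` as `u -> 0`. Used to
#' bound barrier-crossing times and to validate the quadrature and
#' simulation machinery.
#'
#' @param ell Distance to travel, nm.
#' @param F_opposing Constant opposing force, pN (may be 0 or negative for
#'   an assisting force).
#' @param D Diffusion coefficient, nm^2/s.
#' @param kBT Thermal energy, pN nm.
#' @return MFPT in s (vectorized over any argument).
#' @export
mfpt_closed_form <- function(ell, F_opposing, D, kBT) {
  if (any(ell <= 0) || any(D <= 0)) {
    stop("mfpt_closed_form: `ell` and `D` must be positive", call. = FALSE)
  }
  u <- F_opposing * ell / kBT
  small <- abs(u) < 1e-8
  ratio <- ifelse(small, 0.5 + u / 6, (expm1(u) - u) / u^2)
  (ell^2 / D) * ratio
}

#' Mean first-passage time by quadrature
#'
#' Numerical double-integral solution of the backward equation for the MFPT
#' of overdamped diffusion in an arbitrary potential on `[a, b]`, with
#' either two absorbing boundaries or a reflecting lower boundary. This is
#' the independent oracle against which the Langevin first-passage
#' simulations are checked, and the root-solving target of
#' [calibrate_reduced_barrier()].
#'
#' @param U Vectorized potential function of position (pN nm).
#' @param a,b Domain boundaries, nm.
#' @param x0 Starting position, nm.
#' @param D Diffusion coefficient, nm^2/s.
#' @param kBT Thermal energy, pN nm.
#' @param boundary `"both_absorbing"` (exit through either side; the
#'   dwell-time setting) or `"reflecting_lower"` (classic escape over `b`).
#' @param n Grid size for the cumulative trapezoids.
#' @return MFPT in s.
#' @export
mfpt_quadrature <- function(U, a, b, x0, D, kBT,
                            boundary = c("both_absorbing", "reflecting_lower"),
                            n = 20001L) {
  boundary <- match.arg(boundary)
  x <- seq(a, b, length.out = n)
  u <- U(x) / kBT
  u <- u - min(u)                       # gauge; cancels in the ratio
  ep <- exp(u)
  em <- exp(-u)
  cum <- function(y) cumsum(c(0, diff(x) * (head(y, -1) + tail(y, -1)) / 2))
  psi <- cum(em)                        # integral of e^{-U/kBT} from a
  if (boundary == "reflecting_lower") {
    integrand <- ep * psi
    I <- cum(integrand)
    tau <- (I[n] - stats::approx(x, I, xout = x0)$y) / D
  } else {
    Iep <- cum(ep)
    Ieppsi <- cum(ep * psi)
    C <- Ieppsi[n] / Iep[n] / D
    tau_x <- Iep * C - Ieppsi / D
    tau <- stats::approx(x, tau_x, xout = x0)$y
  }
  tau
}

minima_positions <- function(pot) {
  sp <- pot$spec
  (seq_len(sp$binding_sites) - 1) * sp$d
}

#' Dwell time in a potential minimum, by quadrature
#'
#' MFPT of a free attached particle (no elastic element) from a minimum of
#' the periodic potential to either adjacent minimum, both directions
#' absorbing — the escape definition used for barrier calibration (an
#' "observed step" is a crossing into a neighbouring minimum, matching the
#' step-detection semantics).
#'
#' @param env A [physical_env()].
#' @param pot A [build_potential()] result.
#' @param start_minimum 0-based index of the starting minimum (default 1,
#'   an interior minimum with neighbours `d` away on both sides).
#' @return Mean dwell time, s.
#' @export
dwell_time_quadrature <- function(env, pot, start_minimum = 1L) {
  mins <- minima_positions(pot)
  if (start_minimum < 1L || start_minimum > length(mins) - 2L) {
    stop("dwell_time_quadrature: `start_minimum` must be an interior minimum",
         call. = FALSE)
  }
  a <- mins[start_minimum]
  b <- mins[start_minimum + 2L]
  mfpt_quadrature(function(x) potential_energy(pot, x), a, b,
                  x0 = mins[start_minimum + 1L],
                  D = diffusion_coefficient(env), kBT = env$kBT,
                  boundary = "both_absorbing")
}

#' Monte-Carlo mean dwell time in a potential minimum
#'
#' Simulates the free attached particle with the Langevin engine and returns
#' the mean residence time before first arrival at either adjacent minimum,
#' over `n_escapes` independent escapes.
#'
#' @inheritParams dwell_time_quadrature
#' @param integ An [integrator_spec()]; its `dt` must satisfy the
#'   steep-face diffusion bound for this potential.
#' @param n_escapes Number of independent escapes (>= 30).
#' @return A list with `mean` (s), `stderr` (s), and the vector `times`.
#' @export
mean_dwell_time <- function(env, pot, integ, n_escapes, start_minimum = 1L) {
  if (n_escapes < 30) {
    stop("mean_dwell_time: use at least 30 escapes", call. = FALSE)
  }
  check_dt(integ, env, pot$spec)
  mins <- minima_positions(pot)
  if (start_minimum < 1L || start_minimum > length(mins) - 2L) {
    stop("mean_dwell_time: `start_minimum` must be an interior minimum",
         call. = FALSE)
  }
  a <- mins[start_minimum]
  b <- mins[start_minimum + 2L]
  bp <- pot$breakpoints
  keep <- bp$x >= a - 1e-12 & bp$x <= b + 1e-12
  times <- cpp_first_passage(
    bx = bp$x[keep], be = bp$energy[keep], a = a, b = b,
    x0 = mins[start_minimum + 1L], reflect_a = FALSE,
    n_escapes = as.integer(n_escapes), gamma_head = env$gamma_head,
    kBT = env$kBT, dt = integ$dt, max_steps = 1e12, seed = integ$seed)
  list(mean = mean(times), stderr = stats::sd(times) / sqrt(length(times)),
       times = times)
}

#' Simulate first passage against a constant force
#'
#' Langevin simulation matching the geometry of [mfpt_closed_form()]: start
#' at a reflecting boundary, absorb after a distance `ell` climbed against a
#' constant force.
#'
#' @param env A [physical_env()].
#' @param ell Distance, nm.
#' @param F_opposing Constant opposing force, pN.
#' @param dt Time step, s.
#' @param n_escapes Number of passages.
#' @param seed Integer seed.
#' @return List with `mean`, `stderr`, `times`.
#' @export
simulate_constant_force_fpt <- function(env, ell, F_opposing, dt, n_escapes,
                                        seed = 1L) {
  times <- cpp_first_passage(
    bx = c(0, ell), be = c(0, F_opposing * ell), a = 0, b = ell, x0 = 0,
    reflect_a = TRUE, n_escapes = as.integer(n_escapes),
    gamma_head = env$gamma_head, kBT = env$kBT, dt = dt,
    max_steps = 1e12, seed = seed)
  list(mean = mean(times), stderr = stats::sd(times) / sqrt(length(times)),
       times = times)
}

#' Calibrate the reduced macroscopic barrier
#'
#' Macroscopic runs reduce the energetic barrier of the periodic potential
#' so that real-time protocols become computable; the reduction is fixed by
#' requiring a target ratio between the dwell time at the single-molecule
#' barrier and the dwell time at the reduced barrier (the model's value is
#' about 150). The dwell times are computed with the full-potential MFPT
#' quadrature (both escape directions), and the barrier is root-solved to
#' the requested ratio.
#'
#' @param env A [physical_env()].
#' @param spec_sme The single-molecule [potential_spec()] (reference
#'   barrier).
#' @param target_ratio Desired dwell-time ratio (> 1); default 150.
#' @param asymmetry_lambda Asymmetry of the reduced-barrier potential
#'   (defaults to the reference value; ensemble presets may use a larger
#'   value, which shifts the calibrated barrier accordingly).
#' @param tol Relative tolerance on the achieved ratio (default 0.001).
#' @return The reduced barrier `B_macro` in pN nm.
#' @export
calibrate_reduced_barrier <- function(env, spec_sme, target_ratio = 150,
                                      asymmetry_lambda = spec_sme$asymmetry_lambda,
                                      tol = 1e-3) {
  if (target_ratio < 1) {
    stop("calibrate_reduced_barrier: `target_ratio` must be >= 1", call. = FALSE)
  }
  if (target_ratio == 1 && asymmetry_lambda == spec_sme$asymmetry_lambda) {
    return(spec_sme$barrier)
  }
  tau_ref <- dwell_time_quadrature(env, build_potential(spec_sme))
  make_spec <- function(B) {
    s <- spec_sme
    s$barrier <- B
    s$asymmetry_lambda <- asymmetry_lambda
    validate_potential_spec(s)
    s
  }
  f <- function(B) {
    log(tau_ref / dwell_time_quadrature(env, build_potential(make_spec(B)))) -
      log(target_ratio)
  }
  lo <- spec_sme$deltaG * 1.001 + 1e-9
  hi <- spec_sme$barrier
  flo <- f(lo)
  fhi <- f(hi)
  if (flo * fhi > 0) {
    stop("calibrate_reduced_barrier: no barrier in (deltaG, B_SME] achieves ",
         "the target dwell-time ratio ", target_ratio, call. = FALSE)
  }
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = env$kBT * tol)
  root$root
}
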
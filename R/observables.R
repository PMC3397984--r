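resolve_trace <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x) && is.data.frame(x$trace)) return(x$trace)
  stop("expected a trace data.frame or a run result containing one",
       call. = FALSE)
}

#' Extract T1 by the tangent method
#'
#' The tension immediately after a fast length step is partially obscured by
#' the earliest recovery; following the classic tangent convention, a line
#' is fitted to the tension over the early-recovery window just after the
#' ramp and extrapolated back to the end-of-ramp time. Its intercept there
#' is T1 (the elastic response).
#'
#' @param x A length-clamp trace (data.frame) or a [run_length_clamp()]
#'   result (from which `t_step`/`ramp` are taken automatically).
#' @param t_step Step start time, s (absolute, same clock as the trace).
#' @param ramp Ramp duration, s.
#' @param window Width of the fitted early-recovery window, s. Keep it
#'   short relative to the fast-recovery time constant (w <= tau/5 keeps
#'   the extrapolation error within about 1 percent).
#' @return T1 in pN.
#' @export
extract_t1 <- function(x, t_step = x$t_step_abs, ramp = x$ramp,
                       window = 2e-4) {
  tr <- resolve_trace(x)
  t0 <- t_step + ramp
  sel <- tr$t_s >= t0 & tr$t_s <= t0 + window
  if (sum(sel) < 5) {
    stop("extract_t1: early-recovery window lies outside the trace",
         call. = FALSE)
  }
  fit <- stats::lm(tension_pN ~ t_s, data = tr[sel, ])
  unname(stats::predict(fit, data.frame(t_s = t0)))
}

#' Extract T2 from the fast-recovery plateau
#'
#' After the fast (millisecond) tension recovery the trace plateaus at T2
#' before the slow creep produced by fresh attachments. The plateau is
#' found by a rolling-slope criterion: the first post-ramp window whose
#' fitted slope is within noise of zero (and whose change over the window
#' is a negligible fraction of the transient amplitude); T2 is the mean
#' tension over that window.
#'
#' @param x A length-clamp trace or [run_length_clamp()] result.
#' @param t_step Step start time, s.
#' @param ramp Ramp duration, s.
#' @param window Rolling window width, s (default 2e-4).
#' @param rel_tol Maximum |slope| * window as a fraction of the transient
#'   amplitude for a window to count as flat (default 0.02).
#' @param nse Additionally accept a window whose slope is within `nse`
#'   standard errors of zero (default 2).
#' @return T2 in pN.
#' @export
extract_t2 <- function(x, t_step = x$t_step_abs, ramp = x$ramp,
                       window = 2e-4, rel_tol = 0.02, nse = 2) {
  tr <- resolve_trace(x)
  t0 <- t_step + ramp
  post <- tr[tr$t_s >= t0, , drop = FALSE]
  if (nrow(post) < 20) {
    stop("extract_t2: too little trace after the step", call. = FALSE)
  }
  dt_s <- stats::median(diff(post$t_s))
  m <- max(5L, floor(window / dt_s))
  amplitude <- max(abs(diff(range(post$tension_pN))), 1e-12)
  starts <- seq(1L, nrow(post) - m, by = max(1L, m %/% 2L))
  diagnostics <- numeric(0)
  for (i in starts) {
    w <- post[i:(i + m - 1L), ]
    fit <- stats::lm(tension_pN ~ t_s, data = w)
    sl <- stats::coef(fit)[2]
    se <- suppressWarnings(summary(fit))$coefficients[2, 2]
    diagnostics <- c(diagnostics, abs(sl) * window / amplitude)
    if (abs(sl) * window <= rel_tol * amplitude || abs(sl) <= nse * se) {
      return(mean(w$tension_pN))
    }
  }
  stop("extract_t2: no plateau detected (min |slope|*window/amplitude = ",
       format(min(diagnostics), digits = 3), "); lengthen the trace or relax ",
       "`rel_tol`", call. = FALSE)
}

#' Extract the steady shortening velocity
#'
#' Fits the linear portion of a shortening trace `Z(t)`: candidate
#' trailing windows are scanned from the full trace down to `min_frac` of
#' it, and the first steady one is fitted. A window counts as steady
#' (linear) when its R^2 reaches `min_r2` — the clean, strongly shortening
#' case — or when the slopes fitted to its two halves agree within
#' tolerance, which covers traces whose thermal backbone wander dominates
#' the displacement (near stall the backbone is a bounded random walk and
#' R^2 is structurally low even though the velocity is perfectly
#' well-defined and near zero). Windows still inside a decelerating
#' transient fail both tests and are skipped. The sign is flipped so that
#' shortening is positive; the slope standard error is attached as
#' attribute `"se"`.
#'
#' @param x A force-clamp trace or [run_force_clamp()] result.
#' @param min_r2 R^2 threshold for the fast path (default 0.99).
#' @param min_frac Smallest admissible window as a fraction of the trace
#'   (default 0.3).
#' @return Velocity in nm/s per half-sarcomere (shortening positive).
#' @export
extract_velocity <- function(x, min_r2 = 0.99, min_frac = 0.3) {
  tr <- resolve_trace(x)
  n <- nrow(tr)
  if (n < 20) stop("extract_velocity: trace too short", call. = FALSE)
  seg_slopes <- function(w, K) {
    cuts <- floor(seq(1, nrow(w) + 1, length.out = K + 1))
    vapply(seq_len(K), function(k) {
      seg <- w[cuts[k]:(cuts[k + 1] - 1L), ]
      unname(stats::coef(stats::lm(Z_nm ~ t_s, data = seg))[2])
    }, numeric(1))
  }
  K <- 6L
  for (frac in seq(0, 1 - min_frac, by = 0.1)) {
    i0 <- max(1L, floor(frac * n) + 1L)
    w <- tr[i0:n, ]
    fit <- stats::lm(Z_nm ~ t_s, data = w)
    sm <- suppressWarnings(summary(fit))
    sl <- stats::coef(fit)[2]
    if (isTRUE(sm$r.squared >= min_r2)) {
      v <- -unname(sl)
      attr(v, "se") <- unname(sm$coefficients[2, 2])
      return(v)
    }
    if (nrow(w) < 8L * K) next
    # steadiness: no significant trend among the slopes of K consecutive
    # segments (robust to the slow thermal wander of the backbone, which
    # keeps R^2 low whenever drift does not dominate diffusion)
    sk <- seg_slopes(w, K)
    tfit <- suppressWarnings(summary(stats::lm(sk ~ seq_len(K))))$coefficients
    if (nrow(tfit) == 2 && abs(tfit[2, 1]) <= 2 * tfit[2, 2]) {
      v <- -mean(sk)
      attr(v, "se") <- stats::sd(sk) / sqrt(K)
      return(v)
    }
  }
  stop("extract_velocity: no steady linear window found", call. = FALSE)
}

#' Count attached and stretched motors
#'
#' @param state A [init_ensemble()] state.
#' @return Named integer vector `c(n_attached, n_stretched)`; a motor is
#'   stretched when attached with strictly positive strain.
#' @export
count_motors <- function(state) {
  s <- state$motors$x - state$Z - state$motors$c
  att <- state$motors$psi == 1L
  c(n_attached = sum(att), n_stretched = sum(att & s > 0))
}

#' Mean strain per attached motor
#'
#' @param state A [init_ensemble()] state.
#' @return Mean of `s_i = x_i - Z - c_i` over attached motors, nm; `NA`
#'   with a warning when no motor is attached.
#' @export
mean_strain <- function(state) {
  s <- state$motors$x - state$Z - state$motors$c
  att <- state$motors$psi == 1L
  if (!any(att)) {
    warning("mean_strain: no attached motors; strain undefined")
    return(NA_real_)
  }
  mean(s[att])
}

#' Occupancy of the permitted minima
#'
#' Fraction of attached heads assigned to each of the permitted minima
#' (nearest minimum of the head position reduced modulo the period),
#' averaged over the requested time window of a trace.
#'
#' @param x An ensemble trace (with `occupancy_m*` columns) or a run
#'   result.
#' @param window Length-2 time window, s; default the final third of the
#'   trace.
#' @return Named numeric vector of fractions summing to 1.
#' @export
occupancy_histogram <- function(x, window = NULL) {
  tr <- resolve_trace(x)
  cols <- grep("^occupancy_m", names(tr), value = TRUE)
  if (length(cols) == 0) {
    stop("occupancy_histogram: trace has no occupancy columns", call. = FALSE)
  }
  if (is.null(window)) {
    window <- c(min(tr$t_s) + 2 / 3 * diff(range(tr$t_s)), max(tr$t_s))
  }
  sel <- tr$t_s >= window[1] & tr$t_s <= window[2]
  tot <- colSums(tr[sel, cols, drop = FALSE])
  if (sum(tot) == 0) {
    stop("occupancy_histogram: no attached heads in the window", call. = FALSE)
  }
  tot / sum(tot)
}

#' Occupancy of a single ensemble state
#'
#' @param state A [init_ensemble()] state.
#' @param spec The [potential_spec()] of the run.
#' @return Integer counts per permitted minimum.
#' @export
state_occupancy <- function(state, spec) {
  L <- potential_period(spec)
  att <- state$motors$psi == 1L
  counts <- integer(spec$binding_sites)
  r <- reduce_mod_period(state$motors$x[att], L)
  run_end <- (spec$binding_sites - 1) * spec$d
  k <- ifelse(r < run_end + spec$d / 2,
              pmin(pmax(round(r / spec$d), 0), spec$binding_sites - 1),
              ifelse(r > L - spec$d / 2, 0, spec$binding_sites - 1))
  for (kk in k) counts[kk + 1L] <- counts[kk + 1L] + 1L
  stats::setNames(counts, paste0("m", seq_len(spec$binding_sites)))
}

#' Direct thermodynamic efficiency
#'
#' Mechanical power out over chemical power in: tension times shortening
#' velocity, divided by the ATP consumption rate times the free energy per
#' ATP.
#'
#' @param tension Mean tension, pN.
#' @param velocity Shortening velocity, nm/s.
#' @param atp_rate Detachments (= ATP consumed) per unit time, 1/s.
#' @param deltaG_ATP Free energy per ATP, pN nm (default 100, about
#'   25 kBT).
#' @return Dimensionless efficiency.
#' @export
efficiency_direct <- function(tension, velocity, atp_rate, deltaG_ATP = 100) {
  work_rate <- tension * velocity
  if (atp_rate <= 0) {
    if (work_rate > 0) {
      stop("efficiency_direct: positive work at zero ATP consumption",
           call. = FALSE)
    }
    return(0)
  }
  work_rate / (atp_rate * deltaG_ATP)
}

#' Flashing-ratchet upper bound on the efficiency
#'
#' The energy the jump process injects is bounded below by the sum of the
#' positive energy changes at the attachment/detachment switches (each event
#' log entry carries the total motor energy just before and just after the
#' flip); dividing the mechanical power by that injection rate gives the
#' physical upper bound of the ratchet efficiency. The `"net"` variant sums
#' all energy changes with sign instead of taking positive parts; the
#' positive-part form is the default and the two are reported together by
#' [efficiency_summary()].
#'
#' @param events Event log data.frame with `t_s`, `E_before`, `E_after`
#'   (from any engine run), restricted to the steady window of interest.
#' @param tension Mean tension over the window, pN.
#' @param velocity Shortening velocity over the window, nm/s.
#' @param timespan Duration of the window, s; default the event-log span.
#' @param variant `"positive"` (default) or `"net"`.
#' @return Dimensionless upper bound.
#' @export
efficiency_bound <- function(events, tension, velocity, timespan = NULL,
                             variant = c("positive", "net")) {
  variant <- match.arg(variant)
  if (nrow(events) == 0) {
    stop("efficiency_bound: no jumps in the window; the bound is undefined",
         call. = FALSE)
  }
  if (is.null(timespan)) timespan <- diff(range(events$t_s))
  if (timespan <= 0) stop("efficiency_bound: empty timespan", call. = FALSE)
  dE <- events$E_after - events$E_before
  injected <- if (variant == "positive") sum(pmax(dE, 0)) else sum(dE)
  if (injected <= 0) {
    stop("efficiency_bound: no net energy injection in the window",
         call. = FALSE)
  }
  tension * velocity / (injected / timespan)
}

#' Steady-state observables of a force-clamp run
#'
#' Convenience extractor: restricts a [run_force_clamp()] result to its
#' steady window (trailing fraction), and reports velocity, mean tension,
#' attachment/strain statistics, ATP rate and the two efficiencies.
#'
#' @param run A [run_force_clamp()] result.
#' @param deltaG_ATP Free energy per ATP, pN nm.
#' @param window_frac Trailing fraction of the trace treated as steady
#'   (default 0.5).
#' @return A one-row data.frame with `beta`, `velocity`, `tension`,
#'   `n_attached`, `n_stretched`, `atp_rate`, `eta_direct`, `eta_bound`,
#'   `eta_bound_net`.
#' @export
efficiency_summary <- function(run, deltaG_ATP = 100, window_frac = 0.5) {
  tr <- run$trace
  t1 <- min(tr$t_s) + (1 - window_frac) * diff(range(tr$t_s))
  w <- tr[tr$t_s >= t1, ]
  v <- extract_velocity(w)
  tension <- mean(w$tension_pN)
  span <- diff(range(w$t_s))
  atp_rate <- (w$atp_cum[nrow(w)] - w$atp_cum[1]) / span
  ev <- run$events[run$events$t_s >= t1, , drop = FALSE]
  eta_b <- tryCatch(efficiency_bound(ev, tension, v, timespan = span),
                    error = function(e) NA_real_)
  eta_bn <- tryCatch(efficiency_bound(ev, tension, v, timespan = span,
                                      variant = "net"),
                     error = function(e) NA_real_)
  data.frame(beta = if (!is.null(run$beta)) run$beta else NA_real_,
             velocity = as.numeric(v), tension = tension,
             n_attached = mean(w$n_attached),
             n_stretched = mean(w$n_stretched),
             atp_rate = atp_rate,
             eta_direct = efficiency_direct(tension, v, atp_rate, deltaG_ATP),
             eta_bound = eta_b, eta_bound_net = eta_bn)
}

#' Power output across a load grid
#'
#' @param beta Load grid (fractions of isometric tension).
#' @param tension Mean tensions, pN.
#' @param velocity Shortening velocities, nm/s.
#' @return data.frame `beta`, `power` (pN nm/s) with the argmax `beta`
#'   attached as attribute `"argmax"`.
#' @export
power_curve <- function(beta, tension, velocity) {
  out <- data.frame(beta = beta, power = tension * velocity)
  attr(out, "argmax") <- beta[which.max(out$power)]
  out
}

#' Time-rescaling factor to real time
#'
#' Macroscopic runs are deliberately faster than real muscle (reduced
#' barrier, scaled rates); reported times are slowed back by the ratio of
#' the simulated to the target unloaded shortening velocity.
#'
#' @param v_sim Simulated unloaded velocity, nm/s.
#' @param v_target Experimental unloaded velocity, nm/s.
#' @return Dimensionless factor (> 1 when the simulation is fast).
#' @export
time_rescale_factor <- function(v_sim, v_target) v_sim / v_target
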
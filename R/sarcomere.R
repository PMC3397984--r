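#' Bundle of specifications driving an ensemble run
#'
#' Collects the physical environment, the (macroscopic) potential, the
#' elastic element, the jump rates and the integrator into one object passed
#' to the protocol runners.
#'
#' @param env A [physical_env()].
#' @param pot A [build_potential()] result (typically built from
#'   [macro_potential_spec()] for ensemble work).
#' @param el An [elastic_spec()].
#' @param rates A [rate_spec()].
#' @param integ An [integrator_spec()].
#' @return An object of class `sarcomere_specs`.
#' @export
sarcomere_specs <- function(env, pot, el, rates, integ) {
  check_dt(integ, env, pot$spec, el, rates)
  structure(list(env = env, pot = pot, el = el, rates = rates, integ = integ),
            class = "sarcomere_specs")
}

#' Macroscopic (reduced-barrier) potential specification
#'
#' Ensemble protocols must cover milliseconds of real dynamics, which the
#' single-molecule barrier makes unaffordable: the model therefore runs the
#' ensembles on a reduced barrier whose dwell time is a fixed factor
#' (about 150) shorter, and correspondingly speeds up the jump rates. The
#' asymmetry is likewise relaxed (default 0.5), which widens the steepest
#' potential face and with it the admissible time step; barrier and
#' asymmetry are free parameters of the time-scale compression, and the
#' barrier is always (re)calibrated here to the requested dwell-time ratio
#' by [calibrate_reduced_barrier()].
#'
#' @param env A [physical_env()].
#' @param base The single-molecule reference [potential_spec()].
#' @param target_ratio Dwell-time compression factor (default 150).
#' @param asymmetry_lambda Asymmetry of the macroscopic potential
#'   (default 0.5).
#' @return A [potential_spec()] with the calibrated reduced barrier.
#' @export
macro_potential_spec <- function(env, base = potential_spec(),
                                 target_ratio = 150,
                                 asymmetry_lambda = 0.5) {
  B <- calibrate_reduced_barrier(env, base, target_ratio,
                                 asymmetry_lambda = asymmetry_lambda)
  out <- base
  out$barrier <- B
  out$asymmetry_lambda <- asymmetry_lambda
  validate_potential_spec(out)
  out
}

#' Initialize a half-sarcomere ensemble
#'
#' `N` parallel heads on a rigid backbone, all initially detached (the
#' rising-phase initial condition), with anchors covering the potential
#' period uniformly: because thick and thin filament periodicities are
#' incommensurate, anchor offsets are effectively uniform over one period.
#' The default placement is stratified, `c_i = (i - 1/2) L / N`, which
#' realizes exact uniform coverage without O(1/sqrt(N)) sampling noise;
#' `placement = "random"` draws them uniformly instead.
#'
#' @param N Number of heads.
#' @param L Potential period, nm.
#' @param seed Seed for random placement (ignored for stratified).
#' @param placement `"stratified"` (default) or `"random"`.
#' @return An object of class `sarcomere_state`: backbone coordinate `Z`
#'   (nm, increasing in the shortening direction, starts at 0), a `motors`
#'   data.frame (`x`, `psi`, `c`, `atp_used`), and time `t` (s).
#' @export
init_ensemble <- function(N, L, seed = 1L,
                          placement = c("stratified", "random")) {
  placement <- match.arg(placement)
  if (N < 1) stop("init_ensemble: `N` must be at least 1", call. = FALSE)
  c_off <- if (placement == "stratified") {
    (seq_len(N) - 0.5) * L / N
  } else {
    set.seed(seed)
    stats::runif(N, 0, L)
  }
  structure(
    list(Z = 0,
         motors = data.frame(x = c_off, psi = 0L, c = c_off, atp_used = 0L),
         t = 0),
    class = "sarcomere_state")
}

#' @export
print.sarcomere_state <- function(x, ...) {
  cat("<sarcomere_state>  N =", nrow(x$motors), "heads;  t =", x$t,
      "s;  Z =", x$Z, "nm\n  attached:", sum(x$motors$psi),
      ";  ATP used:", sum(x$motors$atp_used), "\n")
  invisible(x)
}

#' Instantaneous tension of an ensemble state
#'
#' Sum of the elastic forces of all heads at their current strains
#' `s_i = x_i - Z - c_i` — the quantity reported in every trace.
#'
#' @param state A [init_ensemble()] state.
#' @param el An [elastic_spec()].
#' @return Tension in pN.
#' @export
ensemble_tension <- function(state, el) {
  s <- state$motors$x - state$Z - state$motors$c
  sum(elastic_force(el, s))
}

run_ensemble_engine <- function(state, specs, duration, mode,
                                F_load = 0, ramp_t0 = 0, ramp_dur = 0,
                                ramp_dZ = 0, jump_model = 1L,
                                freeze_heads = FALSE, seed = NULL) {
  integ <- specs$integ
  if (!is.null(seed)) integ$seed <- as.integer(seed)
  pot <- specs$pot
  sp <- pot$spec
  n_steps <- floor(duration / integ$dt)
  res <- cpp_simulate_ensemble(
    bx = pot$breakpoints$x, be = pot$breakpoints$energy, L = pot$period,
    allowed_end = sp$binding_sites * sp$d, d_spacing = sp$d,
    n_bind = sp$binding_sites,
    kp = specs$el$kappa_plus, km = specs$el$kappa_minus,
    f1 = specs$rates$f1, g1 = specs$rates$g1, g2 = specs$rates$g2,
    rate_scale = specs$rates$rate_scale,
    attach_window = specs$rates$attach_window,
    gamma_head = specs$env$gamma_head, kBT = specs$env$kBT,
    Gb = specs$env$Gamma_backbone,
    dt = integ$dt, n_steps_d = n_steps, stride = integ$record_stride,
    mode = mode, F_load = F_load,
    ramp_t0 = ramp_t0, ramp_dur = ramp_dur, ramp_dZ = ramp_dZ,
    jump_model = jump_model, freeze_heads = freeze_heads, Fext_head = 0,
    Z0 = state$Z, x_init = state$motors$x,
    psi_init = as.integer(state$motors$psi), c_off = state$motors$c,
    atp_init = as.integer(state$motors$atp_used),
    seed = integ$seed, record_x = FALSE)

  occ <- res$trace$occ
  colnames(occ) <- paste0("occupancy_m", seq_len(ncol(occ)))
  trace <- data.frame(t_s = res$trace$t_s + state$t,
                      Z_nm = -res$trace$Zb_nm,
                      tension_pN = res$trace$tension_pN,
                      n_attached = res$trace$n_attached,
                      n_stretched = res$trace$n_stretched,
                      occ,
                      atp_cum = res$trace$atp_cum)
  ev <- events_df(res$events)
  ev$t_s <- ev$t_s + state$t
  new_state <- structure(
    list(Z = res$Z_final,
         motors = data.frame(x = res$x_final, psi = res$psi_final,
                             c = state$motors$c, atp_used = res$atp_final),
         t = state$t + n_steps * integ$dt),
    class = "sarcomere_state")
  list(trace = trace, events = ev, state = new_state)
}

#' Isometric contraction
#'
#' Runs the full engine with the backbone held fixed, from the given state
#' (typically all-detached: the rising phase). The isometric plateau
#' tension `T0` is estimated as the mean tension over the final third of
#' the run.
#'
#' @param state A [init_ensemble()] state.
#' @param specs A [sarcomere_specs()] bundle.
#' @param duration Simulated time, s.
#' @param seed Optional integer overriding the integrator seed.
#' @return A list with `trace`, `events`, the final `state`, and `T0` (pN).
#' @export
run_isometric <- function(state, specs, duration, seed = NULL) {
  out <- run_ensemble_engine(state, specs, duration, mode = 0L, seed = seed)
  n <- nrow(out$trace)
  out$T0 <- mean(out$trace$tension_pN[out$trace$t_s >=
                                        state$t + 2 / 3 * duration])
  out
}

#' Length-clamp protocol (tension transients)
#'
#' From an isometric steady state, applies a length step `delta` per
#' half-sarcomere as a fast linear ramp at time `t_step` after
#' the phase start, and records tension densely for T1/T2 extraction.
#' Negative `delta` is a release.
#'
#' @param state Pre-equilibrated [init_ensemble()] state (run
#'   [run_isometric()] first).
#' @param specs A [sarcomere_specs()] bundle.
#' @param delta Length step, nm (per half-sarcomere; negative = release).
#' @param t_step Step time after phase start, s.
#' @param duration Total phase duration, s.
#' @param ramp Ramp duration, s (default 1e-6; the experimental
#'   100-microsecond step divided by the same 150-fold time compression the
#'   macroscopic runs apply to every rate, so the step stays fast relative
#'   to the fast tension recovery).
#' @param freeze_heads If `TRUE`, head positions and the jump process are
#'   frozen so that only the backbone moves — the purely elastic reference
#'   in which `T1 - T0 = delta * sum(kappa(s_i))` exactly.
#' @param seed Optional integer seed override.
#' @return A list with `trace`, `events`, final `state`, plus `delta`,
#'   `t_step_abs` and `ramp` for the extractors.
#' @export
run_length_clamp <- function(state, specs, delta, t_step = 5e-4,
                             duration = 2e-3, ramp = 1e-6,
                             freeze_heads = FALSE, seed = NULL) {
  out <- run_ensemble_engine(state, specs, duration, mode = 0L,
                             ramp_t0 = t_step, ramp_dur = ramp,
                             ramp_dZ = -delta,
                             jump_model = if (freeze_heads) 0L else 1L,
                             freeze_heads = freeze_heads, seed = seed)
  out$delta <- delta
  out$t_step_abs <- state$t + t_step
  out$ramp <- ramp
  out
}

#' Force-clamp (isotonic) protocol
#'
#' From an isometric steady state, releases the backbone against a constant
#' load `beta * T0`: the backbone obeys
#' `Gamma_backbone * dZ/dt = tension - beta * T0` (its thermal noise is
#' negligible at the backbone drag scale and is omitted). Records the
#' shortening trace for velocity extraction.
#'
#' @param state Pre-equilibrated [init_ensemble()] state.
#' @param specs A [sarcomere_specs()] bundle.
#' @param beta Load relative to isometric tension, in `[0, 2.5]`.
#' @param T0 Isometric tension, pN (from [run_isometric()]).
#' @param duration Phase duration, s.
#' @param seed Optional integer seed override.
#' @param jump_model `"huxley"` (default) for the search-and-catch/Huxley
#'   rates; `"equilibrium"` for detailed-balance Metropolis switching (the
#'   null model in which no directed motion can arise); `"none"`.
#' @return A list with `trace`, `events`, final `state`, and `beta`.
#' @export
run_force_clamp <- function(state, specs, beta, T0, duration = 2e-3,
                            seed = NULL,
                            jump_model = c("huxley", "equilibrium", "none")) {
  jump_model <- match.arg(jump_model)
  if (beta < 0 || beta > 2.5) {
    stop("run_force_clamp: `beta` must lie in [0, 2.5]", call. = FALSE)
  }
  out <- run_ensemble_engine(state, specs, duration, mode = 1L,
                             F_load = beta * T0, seed = seed,
                             jump_model = switch(jump_model, none = 0L,
                                                 huxley = 1L,
                                                 equilibrium = 2L))
  out$beta <- beta
  out
}

trial_seed <- function(master_seed, trial, phase = 0L) {
  as.integer((as.double(master_seed) * 100003 + trial * 101 + phase) %%
               .Machine$integer.max)
}

#' Run a protocol over independent trials
#'
#' Executes `n_trials` seeded replicates of the declared protocol, each
#' starting from a fresh all-detached ensemble settled isometrically before
#' the protocol phase, and returns per-trial outputs plus mean and SD
#' summaries (the 11-trial convention of all reported observables).
#'
#' @param specs A [sarcomere_specs()] bundle.
#' @param protocol A [protocol_spec()].
#' @param master_seed Integer; per-trial seeds are derived from it by
#'   counter, so the full replicate set is reproducible.
#' @param N Number of heads (default 64).
#' @param settle Isometric settling time before the protocol phase, s.
#' @return A list with `trials` (list of per-trial results, each carrying
#'   `trace`, `events`, `T0` and kind-specific fields) and `summary`
#'   (data.frame of per-trial headline numbers with a mean and SD row
#'   attached as attributes `mean` and `sd`).
#' @export
run_protocol <- function(specs, protocol, master_seed = 1L, N = 64L,
                         settle = 4e-3) {
  validate_protocol_spec(protocol)
  L <- potential_period(specs$pot$spec)
  trials <- vector("list", protocol$n_trials)
  for (k in seq_len(protocol$n_trials)) {
    st <- init_ensemble(N, L)
    iso <- run_isometric(st, specs, settle, seed = trial_seed(master_seed, k, 0L))
    res <- switch(
      protocol$kind,
      isometric = iso,
      length_clamp = {
        r <- run_length_clamp(iso$state, specs, delta = protocol$delta,
                              t_step = if (is.null(protocol$t_step)) 5e-4
                                       else protocol$t_step,
                              duration = protocol$duration,
                              seed = trial_seed(master_seed, k, 1L))
        r$T0 <- iso$T0
        r$iso_trace <- iso$trace
        r
      },
      force_clamp = {
        r <- run_force_clamp(iso$state, specs, beta = protocol$beta,
                             T0 = iso$T0, duration = protocol$duration,
                             seed = trial_seed(master_seed, k, 1L))
        r$T0 <- iso$T0
        r$iso_trace <- iso$trace
        r
      })
    trials[[k]] <- res
  }
  summary_df <- data.frame(
    trial = seq_len(protocol$n_trials),
    T0 = vapply(trials, function(r) r$T0, numeric(1)))
  if (protocol$kind == "force_clamp") {
    summary_df$velocity <- vapply(trials, function(r)
      extract_velocity(r$trace), numeric(1))
  }
  attr(summary_df, "mean") <- colMeans(summary_df[-1])
  attr(summary_df, "sd") <- vapply(summary_df[-1], stats::sd, numeric(1))
  list(trials = trials, summary = summary_df, protocol = protocol)
}
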
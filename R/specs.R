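#' Physical environment of the simulation
#'
#' Bundles the thermal energy and the drag coefficients of the three moving
#' bodies in the model: the myosin head, the micro-needle of the
#' single-molecule set-up, and the thick-filament backbone of the
#' half-sarcomere. Units are fixed throughout the package: energies in
#' pN nm, forces in pN, lengths in nm, times in s, drags in pN s/nm.
#'
#' @param kBT Thermal energy, pN nm. Default 4.1 (T of about 297 K).
#' @param gamma_head Drag coefficient of one myosin head, pN s/nm.
#' @param Gamma_needle Drag coefficient of the micro-needle, pN s/nm. Must be
#'   at least 100 times `gamma_head`; the experimental needle is about three
#'   orders of magnitude heavier than the molecule.
#' @param Gamma_backbone Drag coefficient of the thick filament, pN s/nm. A
#'   scale parameter; normalized ensemble observables do not depend on it.
#' @return An object of class `physical_env`.
#' @examples
#' env <- physical_env()
#' diffusion_coefficient(env)
#' @export
physical_env <- function(kBT = 4.1,
                         gamma_head = 1.9e-7,
                         Gamma_needle = 1.9e-4,
                         Gamma_backbone = 64 * 100 * 1.9e-7) {
  env <- structure(
    list(kBT = kBT, gamma_head = gamma_head,
         Gamma_needle = Gamma_needle, Gamma_backbone = Gamma_backbone),
    class = "physical_env"
  )
  validate_physical_env(env)
  env
}

validate_physical_env <- function(env) {
  for (f in c("kBT", "gamma_head", "Gamma_needle", "Gamma_backbone")) {
    v <- env[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("physical_env: field `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (env$Gamma_needle < 100 * env$gamma_head) {
    stop("physical_env: `Gamma_needle` must be at least 100 x `gamma_head` ",
         "(the needle drag is orders of magnitude above the head drag)",
         call. = FALSE)
  }
  invisible(env)
}

#' Free diffusion coefficient of the head
#'
#' Einstein relation D = kBT / gamma for the overdamped head.
#'
#' @param env A [physical_env()].
#' @return Diffusion coefficient in nm^2/s.
#' @export
diffusion_coefficient <- function(env) env$kBT / env$gamma_head

#' Geometry and energetics of the periodic actomyosin potential
#'
#' Describes one period of the multistable actomyosin landscape: a run of
#' `binding_sites` minima spaced `d` apart and descending by `deltaG` per
#' forward step, separated by barriers of height `barrier`, followed by a
#' steric attachment-forbidden span covering the remaining monomers where the
#' landscape climbs back so that it is flat on average (zero net drop per
#' period).
#'
#' @param d Spacing of the minima, nm; compatible with the actin monomer
#'   diameter (default 5.5).
#' @param monomers_per_period Actin monomers per period (default 6); the
#'   period is `L = monomers_per_period * d`.
#' @param binding_sites Number of monomers the head can bind (default 4);
#'   must be smaller than `monomers_per_period`.
#' @param deltaG Energy bias per forward step between consecutive minima,
#'   pN nm, non-negative. Default 8.2 (= 2 kBT), the value the bias
#'   calibration targets.
#' @param barrier Height B of each maximum above its departing minimum,
#'   pN nm; must exceed `deltaG`. Default 41 (= 10 kBT), the single-molecule
#'   value; macroscopic runs use a reduced barrier from
#'   [calibrate_reduced_barrier()].
#' @param asymmetry_lambda Fraction of `d`, in (0,1), at which the maximum
#'   between consecutive minima sits, measured from the departing minimum.
#'   Small values put the steep face first (default 0.1).
#' @param forward_sign +1 (default) or -1. With -1 the geometry is mirrored
#'   (maximum at fraction `1 - asymmetry_lambda`), a switch kept for
#'   sensitivity tests of the orientation convention.
#' @return An object of class `potential_spec`.
#' @seealso [build_potential()]
#' @export
potential_spec <- function(d = 5.5,
                           monomers_per_period = 6L,
                           binding_sites = 4L,
                           deltaG = 8.2,
                           barrier = 41,
                           asymmetry_lambda = 0.1,
                           forward_sign = 1) {
  spec <- structure(
    list(d = d,
         monomers_per_period = as.integer(monomers_per_period),
         binding_sites = as.integer(binding_sites),
         deltaG = deltaG, barrier = barrier,
         asymmetry_lambda = asymmetry_lambda,
         forward_sign = forward_sign),
    class = "potential_spec"
  )
  validate_potential_spec(spec)
  spec
}

validate_potential_spec <- function(spec) {
  num1 <- function(f) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("potential_spec: field `", f, "` must be a single finite number",
           call. = FALSE)
    }
    v
  }
  if (num1("d") <= 0) stop("potential_spec: `d` must be positive", call. = FALSE)
  if (num1("monomers_per_period") < 2) {
    stop("potential_spec: `monomers_per_period` must be at least 2", call. = FALSE)
  }
  if (num1("binding_sites") < 1 ||
      spec$binding_sites >= spec$monomers_per_period) {
    stop("potential_spec: `binding_sites` must be in [1, `monomers_per_period`)",
         call. = FALSE)
  }
  if (num1("deltaG") < 0) {
    stop("potential_spec: `deltaG` must be non-negative", call. = FALSE)
  }
  if (num1("barrier") <= spec$deltaG) {
    stop("potential_spec: `barrier` must exceed `deltaG`", call. = FALSE)
  }
  lam <- num1("asymmetry_lambda")
  if (lam <= 0 || lam >= 1) {
    stop("potential_spec: `asymmetry_lambda` must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (!spec$forward_sign %in% c(-1, 1)) {
    stop("potential_spec: `forward_sign` must be +1 or -1", call. = FALSE)
  }
  invisible(spec)
}

#' Period length of a potential spec
#' @param spec A [potential_spec()].
#' @return Period L in nm.
#' @export
potential_period <- function(spec) spec$monomers_per_period * spec$d

#' Asymmetric elastic element of the myosin head
#'
#' The series elasticity of the globular portion, lever domain and tail is
#' piecewise linear with different stiffness when stretched
#' (`kappa_plus`) and when compressed (`kappa_minus`); the compressed
#' stiffness is a free parameter of the model and is much softer.
#'
#' @param kappa_plus Stiffness when stretched, pN/nm (default 2.8).
#' @param kappa_minus Stiffness when compressed, pN/nm; `0 <= kappa_minus <=
#'   kappa_plus` (default 0.28).
#' @return An object of class `elastic_spec`.
#' @export
elastic_spec <- function(kappa_plus = 2.8, kappa_minus = 0.28) {
  el <- structure(list(kappa_plus = kappa_plus, kappa_minus = kappa_minus),
                  class = "elastic_spec")
  validate_elastic_spec(el)
  el
}

validate_elastic_spec <- function(el) {
  if (!is.numeric(el$kappa_plus) || length(el$kappa_plus) != 1L ||
      !is.finite(el$kappa_plus) || el$kappa_plus <= 0) {
    stop("elastic_spec: `kappa_plus` must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(el$kappa_minus) || length(el$kappa_minus) != 1L ||
      !is.finite(el$kappa_minus) || el$kappa_minus < 0 ||
      el$kappa_minus > el$kappa_plus) {
    stop("elastic_spec: `kappa_minus` must satisfy 0 <= kappa_minus <= kappa_plus",
         call. = FALSE)
  }
  invisible(el)
}

#' State of one myosin head
#'
#' @param x Head position along the filament axis, nm.
#' @param psi Attachment flag: 0 detached, 1 attached.
#' @param c Anchor offset on the backbone, nm in `[0, L)`; the anchor sits at
#'   `z = Z + c` where `Z` is the backbone position.
#' @param atp_used ATP molecules consumed so far (one per detachment).
#' @return An object of class `motor_state`.
#' @export
motor_state <- function(x = 0, psi = 0L, c = 0, atp_used = 0L) {
  if (!psi %in% c(0L, 1L)) {
    stop("motor_state: `psi` must be 0 (detached) or 1 (attached)", call. = FALSE)
  }
  if (atp_used < 0) stop("motor_state: `atp_used` must be non-negative", call. = FALSE)
  structure(list(x = x, psi = as.integer(psi), c = c,
                 atp_used = as.integer(atp_used)),
            class = "motor_state")
}

#' Attachment/detachment rate functions of the jump process
#'
#' The attachment rate implements the Brownian search-and-catch rule: a
#' detached head binds at the maximal rate `f1` only while thermal
#' fluctuations stretch its elastic element forward by up to `attach_window`
#' and the head sits over a permitted actin monomer. The detachment rate has
#' the 1957 Huxley shape: a large constant rate `g2` at non-positive strain,
#' and a rate growing linearly with positive strain up to the cap `g1`.
#' `rate_scale` is the uniform speed-up applied in macroscopic runs, where
#' the barrier reduction makes the simulated kinetics faster than real time.
#'
#' @param f1 Maximal attachment rate, 1/s (default 6000; about 150 times the
#'   realistic value, matching the macroscopic time compression).
#' @param attach_window Strain window delta_a for attachment, nm (default
#'   5.5, one monomer spacing).
#' @param g1 Detachment rate cap at large positive strain, 1/s (default 1500,
#'   the 1957 Huxley value scaled by the same 150-fold compression as `f1`).
#' @param g2 Detachment rate at non-positive strain, 1/s (default 3000);
#'   must be >= `g1`.
#' @param rate_scale Dimensionless multiplier applied to all rates
#'   (default 1).
#' @return An object of class `rate_spec`.
#' @seealso [attach_rate()], [detach_rate()]
#' @export
rate_spec <- function(f1 = 6000, attach_window = 5.5, g1 = 1500, g2 = 3000,
                      rate_scale = 1) {
  rs <- structure(list(f1 = f1, attach_window = attach_window,
                       g1 = g1, g2 = g2, rate_scale = rate_scale),
                  class = "rate_spec")
  validate_rate_spec(rs)
  rs
}

validate_rate_spec <- function(rs) {
  for (f in c("f1", "attach_window", "g1", "g2", "rate_scale")) {
    v <- rs[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("rate_spec: field `", f, "` must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (rs$attach_window <= 0) {
    stop("rate_spec: `attach_window` must be positive", call. = FALSE)
  }
  if (rs$g2 < rs$g1) {
    stop("rate_spec: `g2` must be at least `g1` (compressed heads detach fastest)",
         call. = FALSE)
  }
  invisible(rs)
}

#' Integrator settings for the Euler-Maruyama scheme
#'
#' The time step must resolve both the elastic relaxation time
#' `gamma_head/kappa_plus` and the diffusion time across the steep face of
#' the potential, `(lambda d)^2 / (2 D)`; the step is required to sit two
#' orders of magnitude below the smaller of the two, and every jump rate `r`
#' must satisfy `r * dt <= 0.01`. Use [max_stable_dt()] to obtain the bound
#' for a given configuration; cross-field validation happens at run time
#' when all the pieces meet.
#'
#' @param dt Time step, s.
#' @param seed Integer master seed; every stochastic routine derives its
#'   stream deterministically from it.
#' @param record_stride Number of integrator steps between stored samples.
#' @return An object of class `integrator_spec`.
#' @export
integrator_spec <- function(dt, seed = 1L, record_stride = 200L) {
  it <- structure(list(dt = dt, seed = as.integer(seed),
                       record_stride = as.integer(record_stride)),
                  class = "integrator_spec")
  validate_integrator_spec(it)
  it
}

validate_integrator_spec <- function(it) {
  if (!is.numeric(it$dt) || length(it$dt) != 1L || !is.finite(it$dt) ||
      it$dt <= 0) {
    stop("integrator_spec: `dt` must be a single positive number", call. = FALSE)
  }
  if (is.na(it$seed)) stop("integrator_spec: `seed` must be an integer", call. = FALSE)
  if (is.na(it$record_stride) || it$record_stride < 1L) {
    stop("integrator_spec: `record_stride` must be a positive integer",
         call. = FALSE)
  }
  invisible(it)
}

#' Largest admissible Euler-Maruyama time step
#'
#' Returns `(1/100) * min(gamma_head/kappa_plus, (lambda d)^2 / (2 D))`,
#' further reduced so that `r * dt <= 0.01` for the fastest jump rate in
#' `rates` (if given).
#'
#' @param env A [physical_env()].
#' @param pot_spec A [potential_spec()], or `NULL` if the head never feels
#'   the potential.
#' @param el An [elastic_spec()], or `NULL` for a free head.
#' @param rates A [rate_spec()], or `NULL` when the jump process is off.
#' @return Upper bound on `dt`, s.
#' @export
max_stable_dt <- function(env, pot_spec = NULL, el = NULL, rates = NULL) {
  D <- diffusion_coefficient(env)
  bounds <- numeric(0)
  if (!is.null(el)) bounds <- c(bounds, env$gamma_head / el$kappa_plus / 100)
  if (!is.null(pot_spec)) {
    ld <- min(pot_spec$asymmetry_lambda, 1 - pot_spec$asymmetry_lambda) *
      pot_spec$d
    bounds <- c(bounds, ld^2 / (2 * D) / 100)
  }
  if (!is.null(rates)) {
    rmax <- max(rates$f1, rates$g1, rates$g2) * rates$rate_scale
    if (rmax > 0) bounds <- c(bounds, 0.01 / rmax)
  }
  if (length(bounds) == 0) {
    stop("max_stable_dt: supply at least one of `pot_spec`, `el`, `rates`",
         call. = FALSE)
  }
  min(bounds)
}

check_dt <- function(it, env, pot_spec = NULL, el = NULL, rates = NULL,
                     what = "integrator.dt") {
  lim <- max_stable_dt(env, pot_spec, el, rates)
  if (it$dt > lim * (1 + 1e-12)) {
    stop(sprintf(paste0("%s = %.3g s exceeds the stability bound %.3g s set by ",
                        "the stiffest of elastic relaxation (gamma_head/kappa_plus), ",
                        "steep-face diffusion ((lambda d)^2/2D) and the jump rates ",
                        "(r*dt <= 0.01)"), what, it$dt, lim), call. = FALSE)
  }
  invisible(TRUE)
}

#' Micro-needle of the single-molecule experiment
#'
#' @param Gamma_needle Needle drag coefficient, pN s/nm (default 1.9e-4,
#'   three orders of magnitude above the head drag).
#' @param kappa_trap Restoring stiffness holding the needle near its rest
#'   position, pN/nm (default 0.1, the mean experimental value; presets
#'   `"low"` = 0.03 and `"high"` = 0.3 cover the two experimental regimes,
#'   see [needle_preset()]).
#' @param kappa_link Symmetric head-needle link stiffness, pN/nm (default
#'   0.3, the classic 1971 crossbridge stiffness scale; the S-1 construct
#'   justifies a symmetric spring here).
#' @param X0 Needle rest position, nm.
#' @return An object of class `needle_spec`.
#' @export
needle_spec <- function(Gamma_needle = 1.9e-4, kappa_trap = 0.1,
                        kappa_link = 0.3, X0 = 0) {
  ns <- structure(list(Gamma_needle = Gamma_needle, kappa_trap = kappa_trap,
                       kappa_link = kappa_link, X0 = X0),
                  class = "needle_spec")
  validate_needle_spec(ns)
  ns
}

validate_needle_spec <- function(ns) {
  for (f in c("Gamma_needle", "kappa_trap", "kappa_link")) {
    v <- ns[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("needle_spec: field `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(ns$X0) || length(ns$X0) != 1L || !is.finite(ns$X0)) {
    stop("needle_spec: `X0` must be a single finite number", call. = FALSE)
  }
  invisible(ns)
}

#' Needle-stiffness presets for the two experimental regimes
#'
#' The oscillating sub-steps were recorded both with soft and with stiff
#' micro-needles; the observed number of steps per ATP cycle differed
#' between the two regimes. `"mean"` is the default calibration stiffness.
#'
#' @param which One of `"low"`, `"mean"`, `"high"`.
#' @param ... Further arguments passed to [needle_spec()].
#' @return A [needle_spec()].
#' @export
needle_preset <- function(which = c("mean", "low", "high"), ...) {
  which <- match.arg(which)
  kt <- switch(which, low = 0.03, mean = 0.1, high = 0.3)
  needle_spec(kappa_trap = kt, ...)
}

#' Ensemble protocol definition
#'
#' @param kind One of `"isometric"`, `"length_clamp"`, `"force_clamp"`.
#' @param delta Length step per half-sarcomere, nm (length clamp only;
#'   negative = release).
#' @param t_step Time of the length step, s.
#' @param beta Load as a fraction of isometric tension, in `[0, 2.5]`
#'   (force clamp only).
#' @param duration Simulated time of the protocol phase, s.
#' @param n_trials Number of independent replicates (default 11, the
#'   convention used for all mean +/- SD summaries).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("isometric", "length_clamp", "force_clamp"),
                          delta = NULL, t_step = NULL, beta = NULL,
                          duration = 4e-3, n_trials = 11L) {
  kind <- match.arg(kind)
  ps <- structure(list(kind = kind, delta = delta, t_step = t_step,
                       beta = beta, duration = duration,
                       n_trials = as.integer(n_trials)),
                  class = "protocol_spec")
  validate_protocol_spec(ps)
  ps
}

validate_protocol_spec <- function(ps) {
  if (!is.numeric(ps$duration) || ps$duration < 0) {
    stop("protocol_spec: `duration` must be non-negative", call. = FALSE)
  }
  if (is.na(ps$n_trials) || ps$n_trials < 1L) {
    stop("protocol_spec: `n_trials` must be a positive integer", call. = FALSE)
  }
  if (ps$kind == "length_clamp") {
    if (is.null(ps$delta) || !is.numeric(ps$delta)) {
      stop("protocol_spec: length clamp requires a numeric `delta` (nm)",
           call. = FALSE)
    }
  }
  if (ps$kind == "force_clamp") {
    if (is.null(ps$beta) || !is.numeric(ps$beta) || ps$beta < 0 ||
        ps$beta > 2.5) {
      stop("protocol_spec: force clamp requires `beta` in [0, 2.5]",
           call. = FALSE)
    }
  }
  invisible(ps)
}

#' @export
print.physical_env <- function(x, ...) {
  cat("<physical_env>  kBT =", x$kBT, "pN nm;  gamma_head =", x$gamma_head,
      "pN s/nm\n  Gamma_needle =", x$Gamma_needle,
      ";  Gamma_backbone =", x$Gamma_backbone, "pN s/nm\n")
  invisible(x)
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec>  d =", x$d, "nm;  period =", potential_period(x),
      "nm (", x$monomers_per_period, "monomers,", x$binding_sites,
      "binding sites )\n  deltaG =", x$deltaG, "pN nm;  barrier =", x$barrier,
      "pN nm;  lambda =", x$asymmetry_lambda, "\n")
  invisible(x)
}

#' @export
print.rate_spec <- function(x, ...) {
  cat("<rate_spec>  f1 =", x$f1, "/s over (0,", x$attach_window,
      "] nm;  g1 =", x$g1, "/s;  g2 =", x$g2, "/s;  scale =", x$rate_scale, "\n")
  invisible(x)
}
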
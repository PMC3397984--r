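#' Specification of a synthetic ground-truth fixture
#'
#' The analysis operations (step detection, T1/T2 extraction, velocity
#' fitting) are validated on deterministic synthetic traces whose ground
#' truth is known by construction, before they are trusted on simulation
#' output.
#'
#' Kinds and their parameters:
#' * `staircase`: `directions` (vector of +1/-1 steps), `step_size` (nm),
#'   `level_duration` (s) — a piecewise-constant position trace.
#' * `exponential_recovery`: `T0`, `A`, `B`, `tau`, `t_step` — tension
#'   `T0` before the step, `A - B exp(-(t - t_step)/tau)` after; the
#'   elastic level is `A - B`, the asymptote `A`.
#' * `two_exponential`: `A`, `B1`, `tau1`, `B2`, `tau2`, `t_step` — a fast
#'   recovery to the intermediate plateau `A - B2`, then slow creep to `A`.
#' * `linear_shortening`: `Z0`, `v` — `Z(t) = Z0 - v t` (shortening
#'   positive by the sign convention of [extract_velocity()]).
#'
#' @param kind One of the four kinds above.
#' @param ... Kind parameters (see list).
#' @param noise_sd Gaussian noise SD added to the signal (default 0).
#' @param seed Seed for the noise.
#' @param dt Sample interval, s (default 1e-5).
#' @param duration Trace length, s (default set per kind).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("staircase", "exponential_recovery",
                                  "two_exponential", "linear_shortening"),
                         ..., noise_sd = 0, seed = 1L, dt = 1e-5,
                         duration = NULL) {
  kind <- match.arg(kind)
  pars <- list(...)
  if (noise_sd < 0) stop("fixture_spec: `noise_sd` must be >= 0", call. = FALSE)
  if (dt <= 0) stop("fixture_spec: `dt` must be positive", call. = FALSE)
  structure(list(kind = kind, pars = pars, noise_sd = noise_sd,
                 seed = as.integer(seed), dt = dt, duration = duration),
            class = "fixture_spec")
}

fixture_par <- function(spec, name, default = NULL) {
  v <- spec$pars[[name]]
  if (is.null(v)) {
    if (is.null(default)) {
      stop("make_fixture: fixture kind `", spec$kind, "` needs parameter `",
           name, "`", call. = FALSE)
    }
    default
  } else v
}

#' Generate a synthetic fixture trace with its ground truth
#'
#' @param spec A [fixture_spec()].
#' @return A list: `trace` (data.frame with `t_s` and the kind's value
#'   column), `truth` (named list of the quantities the analysis operation
#'   should recover), and `spec`.
#' @export
make_fixture <- function(spec) {
  dt <- spec$dt
  out <- switch(
    spec$kind,
    staircase = {
      dirs <- fixture_par(spec, "directions")
      d <- fixture_par(spec, "step_size", 5.5)
      ld <- fixture_par(spec, "level_duration", 2e-3)
      n_lev <- length(dirs) + 1L
      duration <- if (is.null(spec$duration)) n_lev * ld else spec$duration
      t <- seq(0, duration, by = dt)
      levels <- cumsum(c(0, dirs)) * d
      idx <- pmin(floor(t / ld) + 1L, n_lev)
      x <- levels[idx]
      list(trace = data.frame(t_s = t, x_nm = x),
           truth = list(n_forward = sum(dirs > 0), n_backward = sum(dirs < 0),
                        step_times = seq_len(length(dirs)) * ld,
                        levels = levels))
    },
    exponential_recovery = {
      T0 <- fixture_par(spec, "T0")
      A <- fixture_par(spec, "A")
      B <- fixture_par(spec, "B")
      tau <- fixture_par(spec, "tau")
      t_step <- fixture_par(spec, "t_step", 1e-3)
      duration <- if (is.null(spec$duration)) t_step + 10 * tau else spec$duration
      t <- seq(0, duration, by = dt)
      y <- ifelse(t < t_step, T0, A - B * exp(-(t - t_step) / tau))
      list(trace = data.frame(t_s = t, tension_pN = y),
           truth = list(T0 = T0, T1 = A - B, asymptote = A, tau = tau,
                        t_step = t_step))
    },
    two_exponential = {
      A <- fixture_par(spec, "A")
      B1 <- fixture_par(spec, "B1")
      tau1 <- fixture_par(spec, "tau1")
      B2 <- fixture_par(spec, "B2")
      tau2 <- fixture_par(spec, "tau2")
      t_step <- fixture_par(spec, "t_step", 5e-4)
      duration <- if (is.null(spec$duration)) t_step + 2 * tau2 else spec$duration
      t <- seq(0, duration, by = dt)
      dtt <- pmax(t - t_step, 0)
      y <- ifelse(t < t_step, A - B1 - B2,
                  A - B1 * exp(-dtt / tau1) - B2 * exp(-dtt / tau2))
      list(trace = data.frame(t_s = t, tension_pN = y),
           truth = list(T1 = A - B1 - B2, plateau = A - B2, asymptote = A,
                        t_step = t_step))
    },
    linear_shortening = {
      Z0 <- fixture_par(spec, "Z0", 0)
      v <- fixture_par(spec, "v")
      duration <- if (is.null(spec$duration)) 2e-3 else spec$duration
      t <- seq(0, duration, by = dt)
      list(trace = data.frame(t_s = t, Z_nm = Z0 - v * t),
           truth = list(v = v))
    })
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    col <- setdiff(names(out$trace), "t_s")[1]
    out$trace[[col]] <- out$trace[[col]] +
      stats::rnorm(nrow(out$trace), 0, spec$noise_sd)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  out$spec <- spec
  out
}
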
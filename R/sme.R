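#' Forward/backward jump counts
#'
#' @param n_forward,n_backward Non-negative integer counts.
#' @return An object of class `jump_counts`.
#' @export
jump_counts <- function(n_forward, n_backward) {
  if (n_forward < 0 || n_backward < 0) {
    stop("jump_counts: counts must be non-negative", call. = FALSE)
  }
  structure(list(n_forward = as.integer(n_forward),
                 n_backward = as.integer(n_backward)),
            class = "jump_counts")
}

#' Simulate the micro-needle single-molecule experiment
#'
#' An always-attached myosin head (the rigor state is ignored; the head
#' oscillates between attached stable states) diffuses in the periodic
#' potential while coupled through a symmetric spring to a micro-needle
#' with a drag coefficient orders of magnitude above the head's. The needle
#' is held near its rest position by the trap stiffness and can carry a
#' constant external load. Because the potential is biased, a long run
#' would end trapped at the lowest minimum where only backward jumps remain
#' possible; each run is therefore terminated the first time the head
#' reaches a lowest minimum of a period, and jump statistics are pooled
#' over many such runs.
#'
#' @param env A [physical_env()].
#' @param pot A [build_potential()] result (single-molecule barrier).
#' @param needle A [needle_spec()].
#' @param integ An [integrator_spec()].
#' @param F_ext Constant external force opposing forward motion, applied to
#'   the needle, pN.
#' @param max_duration Wall-clock cap per run, s; runs that have not
#'   reached the lowest minimum by then are returned with
#'   `completed = FALSE` (their jump counts remain usable).
#' @param x0 Initial head position, nm (default 0, the highest minimum).
#' @param hysteresis Band around a minimum within which the head must be
#'   found to be (re)assigned, nm; default `d/4`.
#' @param filter_window Running-median width (samples) for the step
#'   counting (default 21).
#' @return A list: `trace` (data.frame `t_s`, `x_nm`, `X_nm`), `counts`
#'   ([jump_counts()]) — the forward/backward steps of the filtered
#'   staircase, the quantity the experiment reports; `hops` (data.frame
#'   `t_s`, `direction`) — the raw minimum-crossing log, which also
#'   contains the sub-microsecond excursions that the stretched link
#'   immediately pulls back and that no filtered trace would count;
#'   `completed`; `t_end`.
#' @export
simulate_sme <- function(env, pot, needle, integ, F_ext = 0,
                         max_duration = 8e-3, x0 = 0,
                         hysteresis = pot$spec$d / 4, filter_window = 21L) {
  link_el <- elastic_spec(kappa_plus = needle$kappa_link,
                          kappa_minus = needle$kappa_link)
  check_dt(integ, env, pot$spec, link_el)
  sp <- pot$spec
  res <- cpp_simulate_sme(
    bx = pot$breakpoints$x, be = pot$breakpoints$energy, L = pot$period,
    d_spacing = sp$d, n_bind = sp$binding_sites,
    gamma_head = env$gamma_head, Gamma_needle = needle$Gamma_needle,
    kBT = env$kBT,
    kappa_link = needle$kappa_link, kappa_trap = needle$kappa_trap,
    X0 = needle$X0, F_ext = F_ext,
    dt = integ$dt, max_steps_d = floor(max_duration / integ$dt),
    stride = integ$record_stride, hysteresis = hysteresis,
    x_start = x0, seed = integ$seed)
  trace <- data.frame(t_s = res$t_s, x_nm = res$x_nm, X_nm = res$X_nm)
  detected <- detect_steps(trace, d = sp$d, filter_window = filter_window,
                           hysteresis = hysteresis, value_col = "x_nm")
  list(trace = trace,
       counts = detected$counts,
       steps = detected$steps,
       hops = data.frame(t_s = res$jump_t, direction = res$jump_dir),
       completed = res$completed, t_end = res$t_end)
}

#' Detect steps in a staircase trace
#'
#' Running-median filtering followed by nearest-level assignment on a grid
#' of spacing `d` (anchored at the initial filtered level) with a
#' hysteresis band: the assignment changes only once the filtered signal
#' has committed to within `d/2 - hysteresis` of a new level. Each change
#' of assigned level is a jump; its direction is the sign of the change.
#'
#' @param trace A data.frame with a time column `t_s` and a position
#'   column (`value_col`).
#' @param d Step size (level spacing), nm; must be positive.
#' @param filter_window Running-median width in samples (odd; default 21).
#' @param hysteresis Band width, nm (default `d/4`).
#' @param value_col Name of the position column (default `"x_nm"`).
#' @return A list: `counts` ([jump_counts()]) and `steps` (data.frame
#'   `t_s`, `direction`, `level`).
#' @export
detect_steps <- function(trace, d, filter_window = 21L, hysteresis = d / 4,
                         value_col = "x_nm") {
  if (d <= 0) stop("detect_steps: `d` must be positive", call. = FALSE)
  y <- trace[[value_col]]
  if (is.null(y)) {
    stop("detect_steps: no column `", value_col, "` in trace", call. = FALSE)
  }
  k <- as.integer(filter_window)
  if (k %% 2L == 0L) k <- k + 1L
  yf <- if (length(y) > k) stats::runmed(y, k) else y
  lev0 <- yf[1]
  commit <- d / 2 - hysteresis
  cur <- 0L
  step_t <- numeric(0)
  step_dir <- integer(0)
  step_lev <- integer(0)
  for (i in seq_along(yf)) {
    kk <- round((yf[i] - lev0) / d)
    if (kk != cur && abs(yf[i] - (lev0 + kk * d)) <= commit) {
      n_jumps <- abs(kk - cur)
      dir <- sign(kk - cur)
      for (j in seq_len(n_jumps)) {
        step_t <- c(step_t, trace$t_s[i])
        step_dir <- c(step_dir, as.integer(dir))
        step_lev <- c(step_lev, cur + as.integer(dir) * j)
      }
      cur <- as.integer(kk)
    }
  }
  list(counts = jump_counts(sum(step_dir > 0), sum(step_dir < 0)),
       steps = data.frame(t_s = step_t, direction = step_dir,
                          level = step_lev))
}

#' Pooled forward/backward jump ratio with bootstrap CI
#'
#' Pools counts across runs and reports `sum(Nf) / sum(Nb)` with a
#' percentile bootstrap confidence interval over runs. With no backward
#' jumps in the pool the point estimate is infinite and the lower
#' confidence bound is the informative number.
#'
#' @param counts A data.frame with columns `n_forward` and `n_backward`,
#'   one row per run (a single [jump_counts()] is accepted).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return A list: `ratio`, `ci` (length 2), `n_forward`, `n_backward`,
#'   `n_runs`.
#' @export
jump_ratio <- function(counts, n_boot = 2000L, conf = 0.95, seed = 1L) {
  if (inherits(counts, "jump_counts")) {
    counts <- data.frame(n_forward = counts$n_forward,
                         n_backward = counts$n_backward)
  }
  nf <- sum(counts$n_forward)
  nb <- sum(counts$n_backward)
  if (nf + nb == 0) {
    stop("jump_ratio: no jumps at all; ratio undefined", call. = FALSE)
  }
  ratio <- nf / nb  # Inf when nb == 0 (lower bound carried by the CI)
  n <- nrow(counts)
  boot <- numeric(n_boot)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b] <- sum(counts$n_forward[idx]) / max(sum(counts$n_backward[idx]), 1e-300)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  list(ratio = ratio, ci = ci, n_forward = nf, n_backward = nb, n_runs = n)
}

#' Constant-force (naive) estimate of the potential bias
#'
#' The historical estimate obtained by assuming the needle applies a
#' constant force F to the motor during a jump: inverting the tilted
#' Boltzmann ratio gives `deltaG = kBT ln(Nf/Nb) + F d`. Because the real
#' needle is far heavier than the head, the instantaneous force varies
#' during a jump and this estimate systematically understates the true
#' bias — quantifying that understatement is what the simulated sweep is
#' for.
#'
#' @param counts A [jump_counts()] (both counts must be positive).
#' @param F Constant opposing force, pN.
#' @param d Step size, nm.
#' @param kBT Thermal energy, pN nm.
#' @return Estimated bias, pN nm.
#' @export
naive_bias_estimate <- function(counts, F, d, kBT) {
  if (counts$n_forward <= 0 || counts$n_backward <= 0) {
    stop("naive_bias_estimate: both counts must be positive", call. = FALSE)
  }
  kBT * log(counts$n_forward / counts$n_backward) + F * d
}

#' Bias-estimation sweep over (deltaG, F)
#'
#' For every bias value on `deltaG_grid` and every external force on
#' `F_grid`, runs `n_runs` terminated single-molecule simulations, pools
#' the forward/backward jump counts, and fits `ln(ratio)` against force
#' per bias value (the exponential fits of the calibration figure). The
#' resulting table is the simulation counterpart of the experimental
#' jump-ratio data: the bias whose fitted curve matches observed ratios is
#' the calibrated bias.
#'
#' @param env A [physical_env()].
#' @param base_spec Reference [potential_spec()]; its `deltaG` is replaced
#'   by each grid value.
#' @param deltaG_grid Bias values, pN nm.
#' @param F_grid External forces, pN.
#' @param needle A [needle_spec()].
#' @param integ An [integrator_spec()]; per-run seeds are derived from its
#'   seed by counter.
#' @param n_runs Terminated simulations per grid point (default 20).
#' @param max_duration Per-run duration cap, s.
#' @return A data.frame with one row per (deltaG, F): `deltaG_pNnm`,
#'   `F_pN`, `n_runs`, `Nf`, `Nb`, `ratio`, `ci_lo`, `ci_hi`,
#'   `fit_slope`, `fit_intercept`, `n_completed`. Per-run counts are
#'   attached as attribute `"runs"`.
#' @export
bias_sweep <- function(env, base_spec, deltaG_grid, F_grid, needle, integ,
                       n_runs = 20L, max_duration = 8e-3) {
  if (length(deltaG_grid) == 0 || length(F_grid) == 0) {
    stop("bias_sweep: grids must be non-empty", call. = FALSE)
  }
  rows <- list()
  run_rows <- list()
  cond <- 0L
  for (dG in deltaG_grid) {
    sp <- base_spec
    sp$deltaG <- dG
    validate_potential_spec(sp)
    pot <- build_potential(sp)
    for (F in F_grid) {
      cond <- cond + 1L
      nf <- integer(n_runs)
      nb <- integer(n_runs)
      compl <- logical(n_runs)
      for (r in seq_len(n_runs)) {
        it <- integ
        it$seed <- trial_seed(integ$seed, cond * 1000L + r)
        sim <- simulate_sme(env, pot, needle, it, F_ext = F,
                            max_duration = max_duration)
        nf[r] <- sim$counts$n_forward
        nb[r] <- sim$counts$n_backward
        compl[r] <- sim$completed
      }
      jr <- jump_ratio(data.frame(n_forward = nf, n_backward = nb),
                       seed = trial_seed(integ$seed, cond))
      rows[[cond]] <- data.frame(
        deltaG_pNnm = dG, F_pN = F, n_runs = n_runs,
        Nf = jr$n_forward, Nb = jr$n_backward, ratio = jr$ratio,
        ci_lo = jr$ci[1], ci_hi = jr$ci[2],
        n_completed = sum(compl))
      run_rows[[cond]] <- data.frame(deltaG_pNnm = dG, F_pN = F,
                                     run = seq_len(n_runs),
                                     n_forward = nf, n_backward = nb,
                                     completed = compl)
    }
  }
  out <- do.call(rbind, rows)
  out$fit_slope <- NA_real_
  out$fit_intercept <- NA_real_
  for (dG in deltaG_grid) {
    sel <- out$deltaG_pNnm == dG & is.finite(out$ratio) & out$ratio > 0
    if (sum(sel) >= 2) {
      fit <- stats::lm(log(ratio) ~ F_pN, data = out[sel, ])
      out$fit_slope[out$deltaG_pNnm == dG] <- stats::coef(fit)[2]
      out$fit_intercept[out$deltaG_pNnm == dG] <- stats::coef(fit)[1]
    }
  }
  attr(out, "runs") <- do.call(rbind, run_rows)
  out
}

#' Calibrate the bias from observed jump ratios
#'
#' Given a sweep table and observed `(F, ratio)` pairs, selects the grid
#' bias whose fitted exponential `ratio(F)` curve is closest to the
#' observations (least squares in log ratio) — the procedure that turns
#' single-molecule jump statistics into the in-vivo energy bias.
#'
#' @param sweep A [bias_sweep()] table.
#' @param observed A data.frame with columns `F_pN` and `ratio`.
#' @return The selected bias, pN nm, with the per-bias distances attached
#'   as attribute `"distance"`.
#' @export
estimate_bias_from_sweep <- function(sweep, observed) {
  grids <- unique(sweep$deltaG_pNnm)
  dist <- vapply(grids, function(dG) {
    row <- sweep[sweep$deltaG_pNnm == dG, ][1, ]
    pred <- row$fit_intercept + row$fit_slope * observed$F_pN
    sum((log(observed$ratio) - pred)^2)
  }, numeric(1))
  out <- grids[which.min(dist)]
  attr(out, "distance") <- stats::setNames(dist, grids)
  out
}
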
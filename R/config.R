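#' Default configuration tree
#'
#' All numeric model parameters live in a structured-text (YAML)
#' configuration with two presets: `"sme"` (single-molecule barrier,
#' fine time step) and `"macro"` (reduced-barrier ensemble conditions;
#' `potential.barrier: auto` means "calibrate to the dwell-time ratio at
#' load time"). Units are fixed: pN, nm, s, pN nm.
#'
#' @param preset `"sme"` or `"macro"`.
#' @return A nested list of defaults.
#' @export
default_config <- function(preset = c("sme", "macro")) {
  preset <- match.arg(preset)
  base <- list(
    env = list(kBT = 4.1, gamma_head = 1.9e-7, Gamma_needle = 1.9e-4,
               Gamma_backbone = 64 * 100 * 1.9e-7),
    potential = list(d = 5.5, monomers_per_period = 6L, binding_sites = 4L,
                     deltaG = 8.2, barrier = 41, asymmetry_lambda = 0.1,
                     forward_sign = 1),
    elastic = list(kappa_plus = 2.8, kappa_minus = 0.28),
    rates = list(f1 = 6000, attach_window = 5.5, g1 = 1500, g2 = 3000,
                 rate_scale = 1),
    integrator = list(dt = 6e-11, seed = 1L, record_stride = 500L),
    needle = list(Gamma_needle = 1.9e-4, kappa_trap = 0.1, kappa_link = 0.3,
                  X0 = 0),
    protocol = list(kind = "isometric", delta = NULL, t_step = 5e-4,
                    beta = NULL, duration = 4e-3, n_trials = 11L),
    ensemble = list(N = 64L, settle = 4e-3, master_seed = 1L,
                    dwell_ratio = 150)
  )
  if (preset == "macro") {
    base$potential$barrier <- "auto"
    base$potential$asymmetry_lambda <- 0.5
    base$integrator$dt <- 5e-10
    base$integrator$record_stride <- 200L
  }
  base
}

deep_merge <- function(base, user, path = character()) {
  for (nm in names(user)) {
    full <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) {
      stop("load_config: unknown key `", full, "`", call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], user[[nm]], c(path, nm))
    } else {
      base[nm] <- list(user[[nm]])  # keeps explicit NULLs in place
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or starts from the preset when `path` is `NULL` or
#' the file is empty), merges it over the preset defaults, resolves
#' `potential.barrier: auto` by dwell-time calibration, builds and
#' validates every specification object, and cross-checks the fields
#' against one another (time step against stiffness, rates and potential
#' geometry; force-clamp load range). Unknown keys and violated
#' constraints are reported by their full key names.
#'
#' @param path Path to a YAML configuration, or `NULL` for pure defaults.
#' @param preset `"sme"` or `"macro"`.
#' @return An object of class `run_config`: the resolved raw list plus
#'   built spec objects (`env`, `potential_spec`, `pot`, `elastic`,
#'   `rates`, `integrator`, `needle`, `protocol`, `ensemble`) and a
#'   content `hash`.
#' @export
load_config <- function(path = NULL, preset = c("sme", "macro")) {
  raw <- default_config(preset)
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("load_config: no such file: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (!is.null(user)) raw <- deep_merge(raw, user)
  }
  env <- physical_env(kBT = raw$env$kBT, gamma_head = raw$env$gamma_head,
                      Gamma_needle = raw$env$Gamma_needle,
                      Gamma_backbone = raw$env$Gamma_backbone)
  p <- raw$potential
  if (identical(p$barrier, "auto")) {
    ref <- potential_spec()  # single-molecule reference geometry
    p$barrier <- calibrate_reduced_barrier(
      env, ref, target_ratio = raw$ensemble$dwell_ratio,
      asymmetry_lambda = p$asymmetry_lambda)
    raw$potential$barrier <- p$barrier
  }
  pspec <- potential_spec(d = p$d, monomers_per_period = p$monomers_per_period,
                          binding_sites = p$binding_sites, deltaG = p$deltaG,
                          barrier = p$barrier,
                          asymmetry_lambda = p$asymmetry_lambda,
                          forward_sign = p$forward_sign)
  el <- elastic_spec(raw$elastic$kappa_plus, raw$elastic$kappa_minus)
  rs <- rate_spec(f1 = raw$rates$f1, attach_window = raw$rates$attach_window,
                  g1 = raw$rates$g1, g2 = raw$rates$g2,
                  rate_scale = raw$rates$rate_scale)
  it <- integrator_spec(dt = raw$integrator$dt, seed = raw$integrator$seed,
                        record_stride = raw$integrator$record_stride)
  ns <- needle_spec(Gamma_needle = raw$needle$Gamma_needle,
                    kappa_trap = raw$needle$kappa_trap,
                    kappa_link = raw$needle$kappa_link, X0 = raw$needle$X0)
  pr <- protocol_spec(kind = raw$protocol$kind, delta = raw$protocol$delta,
                      t_step = raw$protocol$t_step, beta = raw$protocol$beta,
                      duration = raw$protocol$duration,
                      n_trials = raw$protocol$n_trials)

  # cross-field constraints, named by key
  D <- diffusion_coefficient(env)
  lim_el <- env$gamma_head / el$kappa_plus / 100
  if (it$dt > lim_el * (1 + 1e-12)) {
    stop("load_config: `integrator.dt` exceeds the elastic bound ",
         format(lim_el, digits = 3), " s set by `elastic.kappa_plus`",
         call. = FALSE)
  }
  ld <- min(pspec$asymmetry_lambda, 1 - pspec$asymmetry_lambda) * pspec$d
  lim_pot <- ld^2 / (2 * D) / 100
  if (it$dt > lim_pot * (1 + 1e-12)) {
    stop("load_config: `integrator.dt` exceeds the diffusion bound ",
         format(lim_pot, digits = 3),
         " s set by `potential.asymmetry_lambda` and `potential.d`",
         call. = FALSE)
  }
  rmax <- max(rs$f1, rs$g1, rs$g2) * rs$rate_scale
  if (rmax > 0 && it$dt > 0.01 / rmax) {
    key <- c("rates.f1", "rates.g1", "rates.g2")[
      which.max(c(rs$f1, rs$g1, rs$g2))]
    stop("load_config: `integrator.dt` = ", format(it$dt, digits = 3),
         " violates rate*dt <= 0.01 for `", key, "`", call. = FALSE)
  }

  structure(list(raw = raw, env = env, potential_spec = pspec,
                 pot = build_potential(pspec), elastic = el, rates = rs,
                 integrator = it, needle = ns, protocol = pr,
                 ensemble = raw$ensemble,
                 hash = config_hash(raw)),
            class = "run_config")
}

#' Save a configuration to YAML
#'
#' Writes the resolved raw configuration; [load_config()] on the result
#' reproduces the configuration exactly.
#'
#' @param cfg A `run_config` (or a raw nested list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "run_config")) cfg$raw else cfg
  yaml::write_yaml(raw, path, precision = 15L)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>  hash", x$hash, "\n")
  print(x$potential_spec)
  print(x$rates)
  cat("  integrator: dt =", x$integrator$dt, "s; seed =", x$integrator$seed,
      "; protocol:", x$protocol$kind, "\n")
  invisible(x)
}

#' FNV-1a content hash of a configuration
#'
#' @param raw A nested list (raw configuration).
#' @return Hex string.
#' @export
config_hash <- function(raw) {
  s <- yaml::as.yaml(raw, precision = 15L)
  bytes <- utf8ToInt(s)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor on the low byte only (b < 256); keeps h a whole double < 2^32
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # multiply mod 2^32 in two 16-bit halves to stay within double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
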
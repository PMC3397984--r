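#' Build the piecewise-linear multistable potential
#'
#' Lays out one period of the actomyosin landscape from a [potential_spec()].
#' With the default orientation the period of length `L = monomers_per_period
#' * d` contains, in forward order: `binding_sites` minima at `0, d, 2d, ...`
#' with energies `0, -deltaG, -2 deltaG, ...`; between consecutive minima a
#' single maximum at fraction `asymmetry_lambda` of `d` from the departing
#' minimum, at `barrier` above it; and, over the attachment-forbidden span,
#' a single return maximum at `(binding_sites + lambda) d` with energy
#' `barrier` above the first minimum, from which the landscape descends
#' linearly back to zero at `L`. The potential is therefore continuous,
#' periodic and flat on average: the per-step bias `deltaG` is paid back
#' entirely over the steric span.
#'
#' @param spec A [potential_spec()].
#' @return An object of class `piecewise_potential`: a list with
#'   `breakpoints` (data.frame of `x` nm, `energy` pN nm over one period,
#'   both endpoints included), `period`, and the generating `spec`.
#' @examples
#' pot <- build_potential(potential_spec())
#' potential_energy(pot, c(0, 5.5, 11, 16.5))   # 0, -8.2, -16.4, -24.6
#' @export
build_potential <- function(spec) {
  validate_potential_spec(spec)
  d <- spec$d
  m <- spec$binding_sites
  M <- spec$monomers_per_period
  dG <- spec$deltaG
  B <- spec$barrier
  lam <- if (spec$forward_sign == 1) spec$asymmetry_lambda else 1 - spec$asymmetry_lambda
  L <- M * d

  k <- seq_len(m) - 1                      # minima indices 0..m-1
  x_min <- k * d
  e_min <- -k * dG
  x_max <- (head_idx <- seq_len(m - 1) - 1) + 0  # maxima between minima
  x_max <- (x_max + lam) * d
  e_max <- -(seq_len(m - 1) - 1) * dG + B

  # return maximum over the forbidden span, then linear descent to (L, 0)
  x_ret <- (m + lam) * d
  e_ret <- B                               # = e_min[m] + (B + (m-1) dG)

  xs <- c(rbind(x_min[seq_len(m - 1)], x_max), x_min[m], x_ret, L)
  es <- c(rbind(e_min[seq_len(m - 1)], e_max), e_min[m], e_ret, 0)

  bp <- data.frame(x = xs, energy = es)
  if (is.unsorted(bp$x, strictly = TRUE)) {
    stop("build_potential: internal error, breakpoints not strictly increasing",
         call. = FALSE)
  }
  structure(list(breakpoints = bp, period = L, spec = spec),
            class = "piecewise_potential")
}

#' @export
print.piecewise_potential <- function(x, ...) {
  cat("<piecewise_potential>  period =", x$period, "nm;",
      nrow(x$breakpoints) - 1, "linear segments\n")
  print(x$breakpoints, row.names = FALSE)
  invisible(x)
}

reduce_mod_period <- function(x, L) {
  r <- x - L * floor(x / L)
  # guard against r == L from floating point
  r[r >= L] <- r[r >= L] - L
  r
}

#' Evaluate the potential energy
#'
#' Linear interpolation on the breakpoint table after reducing `x` modulo the
#' period; the potential is globally flat, so the value repeats identically
#' every period.
#'
#' @param pot A [build_potential()] result.
#' @param x Position(s), nm; vectorized.
#' @return Energy in pN nm.
#' @export
potential_energy <- function(pot, x) {
  r <- reduce_mod_period(x, pot$period)
  stats::approx(pot$breakpoints$x, pot$breakpoints$energy, xout = r,
                method = "linear", ties = "ordered")$y
}

#' Force exerted by the potential
#'
#' Minus the slope of the active linear segment. At a breakpoint the
#' forward-side segment is used — a deterministic tie-break on a
#' measure-zero set.
#'
#' @inheritParams potential_energy
#' @return Force in pN (vectorized).
#' @export
potential_force <- function(pot, x) {
  r <- reduce_mod_period(x, pot$period)
  bp <- pot$breakpoints
  slope <- diff(bp$energy) / diff(bp$x)
  idx <- findInterval(r, bp$x, rightmost.closed = FALSE)
  idx[idx > length(slope)] <- length(slope)
  idx[idx < 1L] <- 1L
  -slope[idx]
}

#' Force of the asymmetric elastic element
#'
#' `kappa_plus * strain` when stretched (`strain > 0`), `kappa_minus *
#' strain` when compressed. This is the force the head exerts on the
#' backbone; positive pulls in the shortening direction.
#'
#' @param el An [elastic_spec()].
#' @param strain Elastic strain(s) `s = x - z`, nm; vectorized.
#' @return Force in pN.
#' @export
elastic_force <- function(el, strain) {
  ifelse(strain > 0, el$kappa_plus, el$kappa_minus) * strain
}

#' Elastic energy stored in the element
#'
#' @inheritParams elastic_force
#' @return Energy in pN nm.
#' @export
elastic_energy <- function(el, strain) {
  0.5 * ifelse(strain > 0, el$kappa_plus, el$kappa_minus) * strain^2
}

#' Is attachment sterically allowed at a position?
#'
#' Binding is permitted only over the first `binding_sites` monomers of each
#' period; the remaining span mimics the steric hindrance of the actin
#' double helix.
#'
#' @param spec A [potential_spec()].
#' @param x Position(s), nm; vectorized.
#' @return Logical vector.
#' @export
attachment_allowed <- function(spec, x) {
  L <- potential_period(spec)
  r <- reduce_mod_period(x, L)
  r < spec$binding_sites * spec$d
}

#' Equilibrium (Boltzmann) density on a grid
#'
#' `exp(-U/kBT)` normalized by trapezoidal quadrature over a finite domain;
#' the equilibrium oracle the stochastic tests compare histograms against.
#'
#' @param pot A [build_potential()] result.
#' @param kBT Thermal energy, pN nm.
#' @param domain Length-2 numeric, nm.
#' @param n Grid size (default 4097).
#' @return A data.frame with columns `x` and `density`; the density
#'   integrates to 1 on the domain.
#' @export
boltzmann_density <- function(pot, kBT, domain, n = 4097L) {
  if (length(domain) != 2L || !all(is.finite(domain)) || diff(domain) <= 0) {
    stop("boltzmann_density: `domain` must be a finite increasing pair",
         call. = FALSE)
  }
  x <- seq(domain[1], domain[2], length.out = n)
  u <- potential_energy(pot, x)
  w <- exp(-(u - min(u)) / kBT)
  Z <- trapz(x, w)
  if (!is.finite(Z) || Z <= 0) {
    stop("boltzmann_density: zero normalization on the requested domain",
         call. = FALSE)
  }
  data.frame(x = x, density = w / Z)
}

#' Boltzmann cumulative distribution on a domain
#'
#' Companion of [boltzmann_density()]: returns a vectorized CDF function,
#' suitable for Kolmogorov-Smirnov comparisons against sampled positions.
#'
#' @inheritParams boltzmann_density
#' @return A function `F(q)`.
#' @export
boltzmann_cdf <- function(pot, kBT, domain, n = 4097L) {
  dens <- boltzmann_density(pot, kBT, domain, n)
  cdf <- cumsum(c(0, diff(dens$x) * (head(dens$density, -1) + tail(dens$density, -1)) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(dens$x, cdf, yleft = 0, yright = 1)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
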
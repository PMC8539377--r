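#' Gaussian beam parameters
#'
#' Describes the illumination beam through its waist radius `w0` (radius of
#' the Gaussian beam at the focus), the third coordinate `r0` of the focal
#' plane, a transverse polarization vector and a complex amplitude. The beam
#' is represented spectrally: its angular spectrum carries the Gaussian
#' weight `exp(-a (k1^2 + k2^2))` with spectral half-width `a = w0^2 / 4`.
#'
#' @param w0_um Waist radius at the focus, micrometres (> 0).
#' @param r0_um Third coordinate of the focal plane, micrometres.
#' @param polarization Real length-2 vector `(p1, p2)`; the third component
#'   of the polarization is zero by construction.
#' @param amplitude Complex overall scale of the spectral envelope. The
#'   physical normalization is arbitrary: every comparison with data is made
#'   after peak normalization.
#' @return An object of class `oct_beam` with fields `w0`, `r0`, `p`
#'   (3-vector), `amplitude` and the derived `a = w0^2/4`.
#' @examples
#' beam_parameters(14.15)
#' @export
beam_parameters <- function(w0_um, r0_um = 0, polarization = c(1, 0),
                            amplitude = 1 + 0i) {
  stop_if_not_finite(c(w0_um, r0_um, polarization), "beam parameters")
  if (w0_um <= 0) stop("w0_um must be positive", call. = FALSE)
  if (length(polarization) != 2L) {
    stop("polarization must be a length-2 real vector (p1, p2)", call. = FALSE)
  }
  structure(
    list(
      w0 = w0_um,
      r0 = r0_um,
      p = c(polarization, 0),
      amplitude = as.complex(amplitude),
      a = w0_um^2 / 4
    ),
    class = "oct_beam"
  )
}

#' @export
print.oct_beam <- function(x, ...) {
  cat(sprintf(
    "Gaussian beam: w0 = %g um (a = %g um^2), focus at x3 = %g um, p = (%g, %g, 0)\n",
    x$w0, x$a, x$r0, x$p[1], x$p[2]
  ))
  invisible(x)
}

#' Wavenumber sweep grid
#'
#' Equally spaced, closed wavenumber grid of a swept-source laser, with the
#' derived band centre `kbar = (kmax + kmin)/2`, half-width
#' `delta = (kmax - kmin)/2` and their reciprocal length scales
#' `sigma_kbar = 1/kbar` and `sigma_delta = 1/delta`.
#'
#' @param kmin,kmax Sweep limits in inverse micrometres, `0 < kmin < kmax`.
#' @param n Number of samples (>= 2); the default 700 matches a typical
#'   swept-source acquisition.
#' @return An object of class `oct_kgrid` with fields `k` (the grid),
#'   `kmin`, `kmax`, `n`, `kbar`, `delta`, `sigma_kbar`, `sigma_delta`.
#' @examples
#' g <- wavenumber_grid(4.7835, 4.8973)
#' g$kbar
#' @export
wavenumber_grid <- function(kmin, kmax, n = 700L) {
  stop_if_not_finite(c(kmin, kmax, n), "wavenumber grid")
  if (!(0 < kmin && kmin < kmax)) stop("need 0 < kmin < kmax", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L) stop("grid needs at least 2 points", call. = FALSE)
  kbar <- (kmax + kmin) / 2
  delta <- (kmax - kmin) / 2
  structure(
    list(
      k = seq(kmin, kmax, length.out = n),
      kmin = kmin, kmax = kmax, n = n,
      kbar = kbar, delta = delta,
      sigma_kbar = 1 / kbar, sigma_delta = 1 / delta
    ),
    class = "oct_kgrid"
  )
}

#' @export
print.oct_kgrid <- function(x, ...) {
  cat(sprintf(
    "wavenumber grid: [%g, %g] 1/um, %d points; kbar = %g, delta = %g\n",
    x$kmin, x$kmax, x$n, x$kbar, x$delta
  ))
  invisible(x)
}

#' Gaussian spectral amplitude of the beam
#'
#' Spectral weight of the angular spectrum at transverse wavevector
#' `(k1, k2)`: `amplitude * exp(-a (k1^2 + k2^2))` inside the propagating
#' disk `k1^2 + k2^2 < k0^2`, and exactly 0 outside (compact-support
#' truncation — evanescent components are never propagated).
#'
#' @param beam An [beam_parameters()] object.
#' @param k1,k2 Transverse wavevector components, 1/um (vectorized).
#' @param k0 Total wavenumber, 1/um (> 0).
#' @return Complex vector of spectral amplitudes.
#' @export
spectral_amplitude <- function(beam, k1, k2, k0) {
  stopifnot(inherits(beam, "oct_beam"))
  stop_if_not_finite(c(k1, k2, k0), "spectral_amplitude inputs")
  if (any(k0 <= 0)) stop("k0 must be positive", call. = FALSE)
  rho2 <- k1^2 + k2^2
  out <- beam$amplitude * exp(-beam$a * rho2)
  out[rho2 >= k0^2] <- 0 + 0i
  out
}

#' Divergence-free polarization lift of a plane-wave component
#'
#' Lifts the transverse polarization `p = (p1, p2, 0)` of one angular-spectrum
#' component to the full 3-vector that makes the plane wave divergence-free:
#' `(1/2) * (p1, p2, +-(p1 k1 + p2 k2)/sqrt(k0^2 - k1^2 - k2^2))`. The sign
#' (`branch`) selects the downward- or upward-propagating branch. By
#' construction the result is orthogonal to the propagation vector
#' `(k1, k2, -+sqrt(k0^2 - k1^2 - k2^2))`.
#'
#' @param p Real 3-vector with third component zero (or a length-2 vector).
#' @param k1,k2 Transverse wavevector components, 1/um (vectorized,
#'   equal length).
#' @param k0 Total wavenumber, 1/um.
#' @param branch `+1` or `-1`.
#' @return A 3 x length(k1) complex matrix (a plain 3-vector for scalar
#'   input).
#' @export
polarization_lift <- function(p, k1, k2, k0, branch = 1) {
  if (length(p) == 2L) p <- c(p, 0)
  if (length(p) != 3L || p[3] != 0) {
    stop("p must have third component zero", call. = FALSE)
  }
  if (!branch %in% c(-1, 1)) stop("branch must be +1 or -1", call. = FALSE)
  rho2 <- k1^2 + k2^2
  if (any(rho2 >= k0^2)) {
    stop("evanescent component: k1^2 + k2^2 must be < k0^2", call. = FALSE)
  }
  kz <- sqrt(k0^2 - rho2)
  v3 <- branch * (p[1] * k1 + p[2] * k2) / kz
  out <- rbind(rep(p[1] / 2, length(k1)), rep(p[2] / 2, length(k1)), v3 / 2)
  if (length(k1) == 1L) as.complex(out[, 1L]) else out
}

#' Incident Gaussian-beam field
#'
#' Evaluates the downward-propagating beam at a point `x` by quadrature of
#' its angular spectrum,
#' `(1/4 pi^2) int g(k1,k2) exp(-i(k1 x1 + k2 x2))
#'   exp(-i sqrt(k0^2-k1^2-k2^2) (r0 - x3)) d(k1,k2)`,
#' where `g` is the polarization lift weighted by the Gaussian spectral
#' amplitude. Integration runs over the square enclosing the disk where the
#' Gaussian weight exceeds 1e-8 of its peak; node counts follow the sampled
#' phase excursion and can be overridden.
#'
#' @param beam An [beam_parameters()] object.
#' @param k0 Wavenumber, 1/um.
#' @param x Evaluation point, length-3, micrometres.
#' @param n_nodes Optional per-axis Gauss-Legendre node count.
#' @return Complex length-3 field vector.
#' @export
incident_field <- function(beam, k0, x, n_nodes = NULL) {
  stopifnot(inherits(beam, "oct_beam"), length(x) == 3L)
  stop_if_not_finite(c(k0, x), "incident_field inputs")
  if (all(beam$p == 0)) return(rep(0 + 0i, 3L))
  rho0 <- min(support_radius(beam), 0.999 * k0)
  lim <- c(-rho0, rho0)
  phase_fun <- function(k1, k2) {
    -(k1 * x[1] + k2 * x[2]) -
      sqrt(pmax(k0^2 - k1^2 - k2^2, 0)) * (beam$r0 - x[3])
  }
  if (is.null(n_nodes)) {
    nn <- auto_gl_nodes(phase_fun, lim, lim)
  } else {
    nn <- rep(as.integer(n_nodes), 2L)
  }
  f <- function(k1, k2) {
    g <- polarization_lift(beam$p, k1, k2, k0, branch = 1)
    if (is.null(dim(g))) g <- matrix(g, nrow = 3L)
    amp <- spectral_amplitude(beam, k1, k2, k0)
    ph <- exp(1i * phase_fun(k1, k2))
    g * rep(amp * ph, each = 3L)
  }
  gl_quad2d(f, lim, lim, nn[1], nn[2], dim = 3L) / (4 * pi^2)
}

# radius where the Gaussian spectral weight drops to 1e-8 of its peak
support_radius <- function(beam) sqrt(log(1e8) / beam$a)
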
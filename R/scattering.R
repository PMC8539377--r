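#' Scan-lens acceptance set
#'
#' Set of transverse wavevectors `(k1, k2)` whose reflected direction
#' `kr / k0` makes an angle of at most `theta_max` with the detection axis
#' `e3`. The exact set is the preimage of a spherical cap under the specular
#' map; for a surface tilted by `theta_Omega` it is well approximated by the
#' rectangle centred at `-k0 sin(2 theta_Omega)` on the `k1` axis with
#' half-widths `L1 = k0 (sin(2 theta_Omega) - sin(2 theta_Omega - theta_max))`
#' and `L2 = k0 sin(theta_max)` (the rectangle circumscribes the nearly
#' circular exact set).
#'
#' @param theta_max_deg Angle of acceptance, degrees, in (0, 90].
#' @param normal Unit surface normal.
#' @param k0 Wavenumber, 1/um.
#' @return An object of class `oct_acceptance` with the rectangle parameters
#'   `center_k1`, `L1`, `L2` and the defining data.
#' @export
acceptance_set <- function(theta_max_deg, normal, k0) {
  if (theta_max_deg <= 0 || theta_max_deg > 90) {
    stop("theta_max_deg must lie in (0, 90]", call. = FALSE)
  }
  if (abs(sum(normal^2) - 1) > 1e-12) {
    stop("normal must be a unit vector", call. = FALSE)
  }
  th_max <- deg2rad(theta_max_deg)
  th_om <- asin(normal[1])
  structure(
    list(
      theta_max_deg = theta_max_deg,
      normal = normal,
      k0 = k0,
      center_k1 = -k0 * sin(2 * th_om),
      L1 = k0 * (-sin(2 * th_om - th_max) + sin(2 * th_om)),
      L2 = k0 * sin(th_max)
    ),
    class = "oct_acceptance"
  )
}

#' @export
print.oct_acceptance <- function(x, ...) {
  cat(sprintf(
    "acceptance set: theta_max = %g deg, k1 in [%g, %g], k2 in [%g, %g] (rectangle)\n",
    x$theta_max_deg, x$center_k1 - x$L1, x$center_k1 + x$L1, -x$L2, x$L2
  ))
  invisible(x)
}

#' Exact membership in the acceptance set
#'
#' `TRUE` where the reflected direction of the propagating component
#' `(k1, k2)` lies within `theta_max` of the `e3` axis, i.e.
#' `kr_3 >= k0 cos(theta_max)`.
#'
#' @param B An [acceptance_set()] object.
#' @param k1,k2 Transverse wavevector components (vectorized).
#' @return Logical vector.
#' @export
acceptance_contains <- function(B, k1, k2) {
  stopifnot(inherits(B, "oct_acceptance"))
  rho2 <- k1^2 + k2^2
  if (any(rho2 >= B$k0^2)) {
    stop("(k1, k2) must be propagating", call. = FALSE)
  }
  kz <- -sqrt(B$k0^2 - rho2)
  dot <- k1 * B$normal[1] + k2 * B$normal[2] + kz * B$normal[3]
  kr3 <- kz - 2 * dot * B$normal[3]
  kr3 >= B$k0 * cos(deg2rad(B$theta_max_deg))
}

#' Phase elements of the single-surface field
#'
#' The three quantities controlling the on-axis closed form of the field
#' reflected by a single tilted surface: `psi0 = r0 - 2 nu3^2 x3`,
#' `psi1 = 2 nu1 nu3 x3`, `psi2 = a + (i/k0)(nu3^2 x3 - r0/2)` and the focus
#' distance `d = nu3^2 x3 - r0/2`. The surface and the beam focus coincide
#' optically when `d = 0` (the reflected beam refocuses at the origin).
#'
#' @param beam An [beam_parameters()] object.
#' @param normal Unit surface normal with second component zero.
#' @param x_omega3 Third coordinate of the surface point, micrometres.
#' @param k0 Wavenumber, 1/um.
#' @return List with `psi0`, `psi1`, `psi2` (complex) and `d`.
#' @export
phase_elements <- function(beam, normal, x_omega3, k0) {
  stopifnot(inherits(beam, "oct_beam"))
  if (normal[2] != 0) stop("normal must lie in the x1-x3 plane", call. = FALSE)
  d <- normal[3]^2 * x_omega3 - beam$r0 / 2
  list(
    psi0 = beam$r0 - 2 * normal[3]^2 * x_omega3,
    psi1 = 2 * normal[1] * normal[3] * x_omega3,
    psi2 = beam$a + 1i * d / k0,
    d = d
  )
}

#' Closed-form magnitude of the single-surface reflected field
#'
#' On-axis magnitude of the field reflected by a single tilted surface under
#' the paraxial root approximation, evaluated in closed form from the
#' Gaussian integrals:
#' `|beta0| k0 / (4 pi sqrt(k0^2 a^2 + d^2)) *
#'   exp(-k0^2 psi1^2 a / (4 (k0^2 a^2 + d^2)))`.
#'
#' @inheritParams phase_elements
#' @param beta0 Amplitude reflection coefficient of the surface.
#' @return Nonnegative field magnitude.
#' @export
closed_form_surface_field <- function(beam, k0, normal, x_omega3, beta0) {
  pe <- phase_elements(beam, normal, x_omega3, k0)
  denom <- k0^2 * beam$a^2 + pe$d^2
  Mod(beta0) * k0 / (4 * pi * sqrt(denom)) *
    exp(-k0^2 * pe$psi1^2 * beam$a / (4 * denom))
}

#' Transverse wavevector feeding a far-field direction
#'
#' For an observation direction `s` (unit vector) and surface normal `nu`,
#' the stationary-phase point of the reflected angular spectrum:
#' `c3 = s3 - 2 <nu, s> nu3` and
#' `(k1, k2) = -k0 sign(c3) (s1 - 2 <nu, s> nu1, s2 - 2 <nu, s> nu2)`.
#' Grazing directions (`c3 = 0`) are rejected.
#'
#' @param s Unit observation direction, length-3.
#' @param normal Unit surface normal.
#' @param k0 Wavenumber, 1/um.
#' @return List with `k1`, `k2`, `c3`.
#' @export
far_field_wavevector <- function(s, normal, k0) {
  if (abs(sum(s^2) - 1) > 1e-10) stop("s must be a unit vector", call. = FALSE)
  dot <- sum(normal * s)
  c3 <- s[3] - 2 * dot * normal[3]
  if (abs(c3) < 1e-12) {
    stop("grazing direction: c3 = 0 has no defined stationary point", call. = FALSE)
  }
  sg <- sign(c3)
  list(
    k1 = -k0 * sg * (s[1] - 2 * dot * normal[1]),
    k2 = -k0 * sg * (s[2] - 2 * dot * normal[2]),
    c3 = c3
  )
}

#' Far-field (stationary-phase) scattered field
#'
#' Dominant term of the scattered field at distance `r` in direction `s`:
#' `-i k0 c3 / (2 pi r) * betaS(k1,k2) f(k1,k2)
#'   exp(-i sqrt(k0^2-k1^2-k2^2) r0) exp(-i <k - kr, xOmega>)
#'   exp(i k0 sign(c3) r)`
#' at the stationary transverse wavevector of [far_field_wavevector()].
#' `r |E|` is exactly independent of `r`, and the magnitude does not depend
#' on the focus position.
#'
#' @param sample An [layered_sample()] object.
#' @param beam An [beam_parameters()] object.
#' @param k0 Wavenumber, 1/um.
#' @param r Observation distance, micrometres (> 0).
#' @param s Unit observation direction.
#' @return Complex scalar field value.
#' @export
scattered_field_far <- function(sample, beam, k0, r, s) {
  if (r <= 0) stop("r must be positive", call. = FALSE)
  ff <- far_field_wavevector(s, sample$normal, k0)
  rho2 <- ff$k1^2 + ff$k2^2
  if (rho2 >= k0^2) stop("stationary point is evanescent", call. = FALSE)
  kz <- -sqrt(k0^2 - rho2)
  k <- c(ff$k1, ff$k2, kz)
  kr <- reflect_wavevector(k, sample$normal)
  beta <- combined_reflection(sample, ff$k1, ff$k2, k0)
  famp <- spectral_amplitude(beam, ff$k1, ff$k2, k0)
  -1i * k0 * ff$c3 / (2 * pi * r) * beta * famp *
    exp(-1i * sqrt(k0^2 - rho2) * beam$r0) *
    exp(-1i * sum((k - kr) * sample$surface_point)) *
    exp(1i * k0 * sign(ff$c3) * r)
}

#' Near-field scattered field by angular-spectrum quadrature
#'
#' Evaluates the reflected field at a point `x` as the superposition of the
#' specularly reflected plane-wave components,
#' `(1/4 pi^2) int_B betaS f exp(-i sqrt(k0^2-k1^2-k2^2) r0)
#'   exp(-i <k - kr, xOmega>) exp(-i <kr, x>) d(k1,k2)`,
#' in scalar mode. `B` is either the full propagating support of the
#' Gaussian envelope (`acceptance = NULL`), the rectangular approximation of
#' the scan-lens acceptance set (`domain = "rect"`, integrated exactly), or
#' the exact acceptance set (`domain = "exact"`, indicator-masked quadrature
#' on its bounding box — slower convergence at the boundary).
#'
#' The stored surface point enters only through the plane it determines:
#' the result is invariant (to quadrature tolerance) under sliding the point
#' within the surface plane.
#'
#' @param sample An [layered_sample()] object.
#' @param beam An [beam_parameters()] object.
#' @param k0 Wavenumber, 1/um.
#' @param x Evaluation point, length-3, micrometres.
#' @param acceptance Optional [acceptance_set()]; `NULL` integrates over the
#'   full Gaussian support.
#' @param domain `"rect"` or `"exact"` (ignored when `acceptance` is NULL).
#' @param n_nodes Optional per-axis node count; default follows the sampled
#'   phase excursion.
#' @return Complex scalar field value.
#' @export
scattered_field_near <- function(sample, beam, k0, x, acceptance = NULL,
                                 domain = c("rect", "exact"), n_nodes = NULL) {
  stopifnot(inherits(sample, "oct_sample"), inherits(beam, "oct_beam"),
    length(x) == 3L)
  domain <- match.arg(domain)
  rho0 <- min(support_radius(beam), 0.999 * k0)
  if (is.null(acceptance)) {
    xlim <- c(-rho0, rho0)
    ylim <- c(-rho0, rho0)
    mask <- NULL
  } else if (domain == "rect") {
    xlim <- acceptance$center_k1 + c(-1, 1) * acceptance$L1
    ylim <- c(-1, 1) * acceptance$L2
    mask <- NULL
  } else {
    grow <- 1.6
    xlim <- acceptance$center_k1 + c(-1, 1) * grow * acceptance$L1
    ylim <- c(-1, 1) * grow * acceptance$L2
    mask <- function(k1, k2) acceptance_contains(acceptance, k1, k2)
  }
  xlim <- pmin(pmax(xlim, -0.999 * k0), 0.999 * k0)
  ylim <- pmin(pmax(ylim, -0.999 * k0), 0.999 * k0)
  nu <- sample$normal
  xo <- sample$surface_point
  phase_fun <- function(k1, k2) {
    kz <- -sqrt(pmax(k0^2 - k1^2 - k2^2, 1e-12))
    dot <- k1 * nu[1] + k2 * nu[2] + kz * nu[3]
    kr1 <- k1 - 2 * dot * nu[1]
    kr2 <- k2 - 2 * dot * nu[2]
    kr3 <- kz - 2 * dot * nu[3]
    -(-kz) * beam$r0 -
      ((k1 - kr1) * xo[1] + (k2 - kr2) * xo[2] + (kz - kr3) * xo[3]) -
      (kr1 * x[1] + kr2 * x[2] + kr3 * x[3])
  }
  if (is.null(n_nodes)) {
    nn <- auto_gl_nodes(phase_fun, xlim, ylim)
  } else {
    nn <- rep(as.integer(n_nodes), 2L)
  }
  f <- function(k1, k2) {
    inside <- k1^2 + k2^2 < k0^2
    out <- rep(0 + 0i, length(k1))
    if (!any(inside)) return(out)
    k1i <- k1[inside]; k2i <- k2[inside]
    val <- combined_reflection(sample, k1i, k2i, k0) *
      spectral_amplitude(beam, k1i, k2i, k0) *
      exp(1i * phase_fun(k1i, k2i))
    if (!is.null(mask)) val[!mask(k1i, k2i)] <- 0 + 0i
    out[inside] <- val
    out
  }
  gl_quad2d(f, xlim, ylim, nn[1], nn[2]) / (4 * pi^2)
}
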
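#' Tilted layered sample
#'
#' Describes the sample as a stack of at most two planar boundaries sharing a
#' unit normal `nu = (sin(tilt), 0, cos(tilt))`, each layer with a constant
#' refractive index. Three types are supported: a perfect mirror (modelled as
#' a reflector flag, not a large finite index), a single dielectric boundary
#' (`interface`) and a parallel-sided slab of thickness `d` (two boundaries,
#' first-order internal reflections only). More than two boundaries are not
#' supported.
#'
#' @param type `"mirror"`, `"interface"` or `"slab"`.
#' @param tilt_deg Tilt of the surface normal away from the x3 axis, degrees.
#' @param n1 Refractive index of the layer below the top boundary (>= 1);
#'   required for `"interface"` and `"slab"`.
#' @param thickness_um Slab thickness in micrometres; required for `"slab"`.
#' @param surface_x3_um Third coordinate of the point where the beam axis
#'   meets the top boundary, micrometres.
#' @return An object of class `oct_sample` with fields `type`, `normal`,
#'   `surface_point`, `tilt_deg`, `n1`, `thickness`, `boundary_offsets`,
#'   `perfect_reflector`.
#' @examples
#' layered_sample("slab", tilt_deg = 2.75, n1 = 1.5088, thickness_um = 150)
#' @export
layered_sample <- function(type = c("mirror", "interface", "slab"),
                           tilt_deg = 0, n1 = NULL, thickness_um = NULL,
                           surface_x3_um = 0) {
  type <- match.arg(type)
  stop_if_not_finite(c(tilt_deg, surface_x3_um), "sample geometry")
  if (abs(tilt_deg) >= 90) stop("tilt must satisfy |tilt| < 90 degrees", call. = FALSE)
  th <- deg2rad(tilt_deg)
  normal <- c(sin(th), 0, cos(th))
  if (type != "mirror") {
    if (is.null(n1) || n1 < 1) stop("n1 >= 1 required for dielectric samples", call. = FALSE)
  } else {
    n1 <- NULL
  }
  if (type == "slab") {
    if (is.null(thickness_um) || thickness_um <= 0) {
      stop("positive thickness_um required for a slab", call. = FALSE)
    }
  } else {
    thickness_um <- NULL
  }
  surface_point <- c(0, 0, surface_x3_um)
  a1 <- sum(surface_point * normal)
  offsets <- if (type == "slab") c(a1, a1 + thickness_um) else a1
  structure(
    list(
      type = type,
      normal = normal,
      surface_point = surface_point,
      tilt_deg = tilt_deg,
      n1 = n1,
      thickness = thickness_um,
      boundary_offsets = offsets,
      perfect_reflector = identical(type, "mirror")
    ),
    class = "oct_sample"
  )
}

#' @export
print.oct_sample <- function(x, ...) {
  extra <- switch(x$type,
    mirror = "perfect reflector",
    interface = sprintf("n1 = %g", x$n1),
    slab = sprintf("n1 = %g, d = %g um", x$n1, x$thickness)
  )
  cat(sprintf(
    "%s sample, tilt %g deg, top surface at x3 = %g um (%s)\n",
    x$type, x$tilt_deg, x$surface_point[3], extra
  ))
  invisible(x)
}

#' Specular reflection of a wavevector
#'
#' Mirror image of `k` across the sample plane:
#' `Phi(k) = k - 2 <k, nu> nu`. An involution that preserves the norm and
#' the tangential component of `k`.
#'
#' @param k Wavevector, length-3 numeric, 1/um.
#' @param normal Unit surface normal (checked to 1e-12).
#' @return The reflected wavevector, length-3.
#' @export
reflect_wavevector <- function(k, normal) {
  stopifnot(length(k) == 3L, length(normal) == 3L)
  if (abs(sum(normal^2) - 1) > 1e-12) {
    stop("normal must be a unit vector (tolerance 1e-12)", call. = FALSE)
  }
  k - 2 * sum(k * normal) * normal
}

#' Fresnel amplitude coefficients at a planar interface
#'
#' Amplitude reflection coefficients for s (perpendicular, TE) and
#' p (parallel, TM) polarization for a plane wave incident from index
#' `n_in` onto index `n_out` with incidence-angle cosine `cos_theta_i`,
#' together with the transmission-angle cosine from Snell's law (complex
#' beyond the critical angle). Sign convention: at normal incidence the
#' perpendicular coefficient from a denser medium is negative,
#' `beta_perp = (n_in - n_out)/(n_in + n_out)`. A perfect reflector is
#' requested with `n_out = Inf`, giving `beta_perp = -1`, `beta_par = +1`.
#'
#' @param n_in,n_out Refractive indices (>= 1, or `n_out = Inf`).
#' @param cos_theta_i Cosine of the incidence angle, in (0, 1].
#' @return An object of class `oct_fresnel`: list with complex `beta_perp`,
#'   `beta_par` and `cos_theta_t`.
#' @examples
#' fresnel_interface(1, 1.5088, 1)$beta_perp  # about -0.2028
#' @export
fresnel_interface <- function(n_in, n_out, cos_theta_i) {
  if (any(cos_theta_i <= 0) || any(cos_theta_i > 1)) {
    stop("cos_theta_i must lie in (0, 1]", call. = FALSE)
  }
  if (n_in < 1) stop("n_in must be >= 1", call. = FALSE)
  if (is.infinite(n_out)) {
    out <- list(
      beta_perp = rep(-1 + 0i, length(cos_theta_i)),
      beta_par = rep(1 + 0i, length(cos_theta_i)),
      cos_theta_t = rep(1 + 0i, length(cos_theta_i))
    )
    class(out) <- "oct_fresnel"
    return(out)
  }
  if (n_out < 1) stop("n_out must be >= 1 (or Inf)", call. = FALSE)
  sin2_t <- (n_in / n_out)^2 * (1 - cos_theta_i^2)
  cos_t <- sqrt(as.complex(1 - sin2_t))
  beta_perp <- (n_in * cos_theta_i - n_out * cos_t) /
    (n_in * cos_theta_i + n_out * cos_t)
  beta_par <- (n_out * cos_theta_i - n_in * cos_t) /
    (n_out * cos_theta_i + n_in * cos_t)
  structure(
    list(beta_perp = beta_perp, beta_par = beta_par, cos_theta_t = cos_t),
    class = "oct_fresnel"
  )
}

#' @export
print.oct_fresnel <- function(x, ...) {
  cat(sprintf(
    "Fresnel coefficients: beta_perp = %s, beta_par = %s, cos(theta_t) = %s\n",
    format(x$beta_perp[1]), format(x$beta_par[1]), format(x$cos_theta_t[1])
  ))
  invisible(x)
}

#' First-order reflection coefficient of a parallel-sided slab
#'
#' Two-boundary coefficient keeping first-order internal reflections only:
#' `beta0 - beta0 (1 - beta0^2) exp(-i k0 2 n1 d cos(theta_t))`, with `beta0`
#' the top-interface amplitude coefficient and `theta_t` the transmission
#' angle inside the slab. At `d = 0` the expression collapses to `beta0^3`
#' (a property of the first-order truncation, not of a vanishing slab).
#'
#' @param beta0 Complex top-interface amplitude reflection coefficient.
#' @param n1 Slab refractive index.
#' @param thickness_d Slab thickness, micrometres (>= 0).
#' @param k0 Wavenumber, 1/um.
#' @param cos_theta_t Transmission-angle cosine.
#' @return Complex reflection coefficient (vectorized over any argument).
#' @export
slab_reflection <- function(beta0, n1, thickness_d, k0, cos_theta_t) {
  if (any(thickness_d < 0)) stop("thickness_d must be >= 0", call. = FALSE)
  beta0 - beta0 * (1 - beta0^2) *
    exp(-1i * k0 * 2 * n1 * thickness_d * cos_theta_t)
}

#' Reflection coefficient of the sample for one plane-wave component
#'
#' Evaluates the sample's amplitude reflection coefficient for the
#' angular-spectrum component `(k1, k2)` of an illumination with wavenumber
#' `k0`, incident from above. In `"scalar"` mode (the canonical detection
#' pathway) this is 1 for a perfect mirror, the perpendicular-polarization
#' Fresnel coefficient of the top boundary for a single interface, and the
#' first-order slab coefficient for two boundaries. Modes `"te"` / `"tm"`
#' return the corresponding polarization's coefficient instead.
#'
#' The incidence-angle cosine is `|<k, nu>| / k0` with
#' `k = (k1, k2, -sqrt(k0^2 - k1^2 - k2^2))`.
#'
#' @param sample An [layered_sample()] object.
#' @param k1,k2 Transverse wavevector components (vectorized, equal length).
#' @param k0 Wavenumber, 1/um.
#' @param mode `"scalar"`, `"te"` or `"tm"`.
#' @return Complex vector of reflection coefficients.
#' @export
combined_reflection <- function(sample, k1, k2, k0,
                                mode = c("scalar", "te", "tm")) {
  stopifnot(inherits(sample, "oct_sample"))
  mode <- match.arg(mode)
  rho2 <- k1^2 + k2^2
  if (any(rho2 >= k0^2)) {
    stop("(k1, k2) must be propagating: k1^2 + k2^2 < k0^2", call. = FALSE)
  }
  if (sample$perfect_reflector) {
    val <- if (mode == "tm") 1 + 0i else if (mode == "te") -1 + 0i else 1 + 0i
    return(rep(val, length(k1)))
  }
  kz <- -sqrt(k0^2 - rho2)
  cos_i <- abs(k1 * sample$normal[1] + k2 * sample$normal[2] +
    kz * sample$normal[3]) / k0
  cos_i <- pmin(cos_i, 1)
  fr <- fresnel_interface(1, sample$n1, cos_i)
  beta0 <- switch(mode, scalar = fr$beta_perp, te = fr$beta_perp,
    tm = fr$beta_par)
  if (identical(sample$type, "interface")) {
    beta0
  } else {
    slab_reflection(beta0, sample$n1, sample$thickness, k0, fr$cos_theta_t)
  }
}
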
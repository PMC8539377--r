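#' Interferometer system geometry
#'
#' Holds the detection-side constants of the interferometer: the scan-lens /
#' detector distance `rD` (sets the reference-field amplitude), the
#' reference-mirror position `xM3`, the angle of acceptance of the scan
#' lens, the complex splitter/loss factor `tau` applied to the sample arm,
#' the product of the reference mirror's reflection coefficient and spectral
#' amplitude at normal incidence (`reference_amplitude`), and the point at
#' which both fields are compared (`detector_point`, defaulting to the
#' origin: an ideal scan lens referenced at the focal-side principal point,
#' so that the common propagation phase over `rD` does not enter the
#' acceptance integral).
#'
#' @param rD_um Detector distance, micrometres (> 0).
#' @param xM3_um Reference-mirror position, micrometres.
#' @param theta_max_deg Angle of acceptance, degrees.
#' @param tau Complex splitter/loss factor for the sample arm.
#' @param reference_amplitude Complex product of reference reflectivity and
#'   spectral amplitude at normal incidence.
#' @param detector_point Length-3 evaluation point for the detected fields.
#' @return An object of class `oct_geometry`.
#' @export
system_geometry <- function(rD_um = 60000, xM3_um = 700,
                            theta_max_deg = 1.5709, tau = 1 + 0i,
                            reference_amplitude = 1 + 0i,
                            detector_point = c(0, 0, 0)) {
  if (rD_um <= 0) stop("rD_um must be positive", call. = FALSE)
  stopifnot(length(detector_point) == 3L)
  structure(
    list(
      rD = rD_um, xM3 = xM3_um, theta_max_deg = theta_max_deg,
      tau = as.complex(tau),
      reference_amplitude = as.complex(reference_amplitude),
      detector_point = detector_point
    ),
    class = "oct_geometry"
  )
}

#' @export
print.oct_geometry <- function(x, ...) {
  cat(sprintf(
    "system geometry: rD = %g um, reference mirror at %g um, theta_max = %g deg\n",
    x$rD, x$xM3, x$theta_max_deg
  ))
  invisible(x)
}

#' Reference-arm field
#'
#' Far-field form of the reference beam reflected by the mirror at `xM3`
#' (normal `e3`, placed in the focus of the reference beam), evaluated at
#' the detector: `-i k0 / (2 pi rD) * reference_amplitude *
#' exp(-i k0 (r0 + x3 - 2 xM3))` where `x3` is the third coordinate of the
#' evaluation point (`rD` by default, reproducing the detector at
#' `xD = rD e3`).
#'
#' @param geometry An [system_geometry()] object.
#' @param beam_ref Reference-arm beam ([beam_parameters()]); only its focus
#'   position `r0` enters the phase.
#' @param k0 Wavenumber, 1/um.
#' @param at Optional evaluation point (length-3); default `c(0, 0, rD)`.
#' @return Complex field value.
#' @export
reference_field <- function(geometry, beam_ref, k0, at = NULL) {
  stopifnot(inherits(geometry, "oct_geometry"), inherits(beam_ref, "oct_beam"))
  x3 <- if (is.null(at)) geometry$rD else at[3]
  -1i * k0 / (2 * pi * geometry$rD) * geometry$reference_amplitude *
    exp(-1i * k0 * (beam_ref$r0 + x3 - 2 * geometry$xM3))
}

#' Dual-balance detector signal
#'
#' Cross-correlation term isolated by dual-balance detection:
#' `-Re(Es * Conj(Er))`, identical to `(|F1|^2 - |F2|^2)/2` for the two
#' fiber fields `F1 = (Es - Er)/sqrt(2)`, `F2 = (i Es + i Er)/sqrt(2)`.
#'
#' @param Es,Er Complex sample and reference field values (vectorized).
#' @return Real signal.
#' @export
dbd_signal <- function(Es, Er) {
  -Re(Es * Conj(Er))
}

#' Reduced A-scan measurement model
#'
#' Single-surface far-field reduction of the detected spectrum:
#' `M(k0) = K k0^2 exp(-k0^2 sigma^2) cos(k0 Theta0)` with
#' `sigma = (w0/2) sin(2 theta_Omega)` (tilt-induced spectral attenuation)
#' and `Theta0` the optical path offset from zero delay.
#'
#' @param params List with fields `K`, `sigma` (um), `Theta0` (um), e.g.
#'   from [reduced_model_params()].
#' @param k0 Wavenumber(s), 1/um.
#' @return Real signal values.
#' @export
reduced_model <- function(params, k0) {
  params$K * k0^2 * exp(-k0^2 * params$sigma^2) * cos(k0 * params$Theta0)
}

#' Parameters of the reduced A-scan model
#'
#' @param K Amplitude scale.
#' @param sigma Tilt attenuation length, micrometres (>= 0); for a beam of
#'   waist `w0` tilted by `theta_Omega`, `sigma = (w0/2) sin(2 theta_Omega)`.
#' @param Theta0 Optical path offset from zero delay, micrometres.
#' @return List of class `oct_reduced_params`.
#' @export
reduced_model_params <- function(K = 1, sigma = 0, Theta0 = 0) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(K = K, sigma = sigma, Theta0 = Theta0),
    class = "oct_reduced_params")
}

#' Simulate one A-scan spectrum
#'
#' For every wavenumber on the sweep grid, computes the acceptance-filtered
#' scattered sample field at the detector point, the reference field at the
#' same point, and their dual-balance cross term. The result is the raw
#' real-valued A-scan spectrum.
#'
#' @param sample An [layered_sample()] object.
#' @param beam An [beam_parameters()] object.
#' @param geometry An [system_geometry()] object.
#' @param grid An [wavenumber_grid()] object.
#' @param n_nodes Per-axis quadrature nodes for the acceptance integral
#'   (default 32, adequate for the narrow acceptance rectangle with the
#'   detector referenced at the origin).
#' @param x1_um Lateral position bookkeeping tag stored with the A-scan.
#' @return An object of class `oct_ascan`: list with `grid`, `signal`,
#'   `x1_um`.
#' @export
simulate_ascan <- function(sample, beam, geometry, grid, n_nodes = 32L,
                           x1_um = 0) {
  stopifnot(inherits(grid, "oct_kgrid"))
  kk <- grid$k
  sig <- numeric(grid$n)
  for (j in seq_len(grid$n)) {
    k0 <- kk[j]
    B <- acceptance_set(geometry$theta_max_deg, sample$normal, k0)
    Es <- geometry$tau *
      scattered_field_near(sample, beam, k0, geometry$detector_point,
        acceptance = B, domain = "rect", n_nodes = n_nodes)
    Er <- reference_field(geometry, beam, k0, at = geometry$detector_point)
    sig[j] <- dbd_signal(Es, Er)
  }
  structure(list(grid = grid, signal = sig, x1_um = x1_um),
    class = "oct_ascan")
}

#' @export
print.oct_ascan <- function(x, ...) {
  cat(sprintf(
    "A-scan: %d samples on [%g, %g] 1/um, x1 = %g um, peak |signal| = %g\n",
    x$grid$n, x$grid$kmin, x$grid$kmax, x$x1_um, max(abs(x$signal))
  ))
  invisible(x)
}

#' Simulate a B-scan (lateral line of A-scans)
#'
#' Raster-scans the beam across the tilted sample: each A-scan is simulated
#' in beam-centred coordinates, with the surface depth advanced by
#' `-tan(tilt) * x1` relative to the depth on the central axis.
#'
#' @inheritParams simulate_ascan
#' @param x1_positions_um Lateral A-scan positions, micrometres.
#' @return An object of class `oct_bscan`: list with `grid`, `x1_um`,
#'   `signals` (n_k x n_ascans matrix) and the per-A-scan surface depths
#'   `surface_x3_um`.
#' @export
simulate_bscan <- function(sample, beam, geometry, grid, x1_positions_um,
                           n_nodes = 32L) {
  tanth <- tan(deg2rad(sample$tilt_deg))
  x3c <- sample$surface_point[3]
  sigs <- matrix(0, nrow = grid$n, ncol = length(x1_positions_um))
  depths <- numeric(length(x1_positions_um))
  for (i in seq_along(x1_positions_um)) {
    x3i <- x3c - tanth * x1_positions_um[i]
    si <- layered_sample(sample$type, tilt_deg = sample$tilt_deg,
      n1 = sample$n1, thickness_um = sample$thickness, surface_x3_um = x3i)
    a <- simulate_ascan(si, beam, geometry, grid, n_nodes = n_nodes,
      x1_um = x1_positions_um[i])
    sigs[, i] <- a$signal
    depths[i] <- x3i
  }
  structure(
    list(grid = grid, x1_um = x1_positions_um, signals = sigs,
      surface_x3_um = depths),
    class = "oct_bscan"
  )
}

#' @export
print.oct_bscan <- function(x, ...) {
  cat(sprintf(
    "B-scan: %d A-scans x %d samples, lateral span [%g, %g] um\n",
    ncol(x$signals), nrow(x$signals), min(x$x1_um), max(x$x1_um)
  ))
  invisible(x)
}
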
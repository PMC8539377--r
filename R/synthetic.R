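#' Recipe for a synthetic power-versus-angle sweep
#'
#' Defaults emulate the goniometer experiment: a mirror tilted in
#' 5-arc-minute steps between -1 and 1 degrees (25 positions), each measured
#' 6 times, with multiplicative Gaussian noise on the power-meter readings.
#'
#' @param angles_deg Angle grid, degrees (strictly increasing).
#' @param repeats Repeats per angle.
#' @param noise_rel Multiplicative noise standard deviation (relative).
#' @param seed Integer seed; fixed seed implies identical output.
#' @return List of class `oct_recipe`.
#' @export
power_angle_recipe <- function(angles_deg = seq(-1, 1, length.out = 25L),
                               repeats = 6L, noise_rel = 0.01, seed = 1L) {
  if (noise_rel < 0) stop("noise_rel must be >= 0", call. = FALSE)
  structure(
    list(kind = "power_angle", angles_deg = angles_deg,
      repeats = as.integer(repeats), noise_rel = noise_rel,
      seed = as.integer(seed)),
    class = "oct_recipe"
  )
}

#' Generate a synthetic power-versus-angle dataset
#'
#' Evaluates the power-versus-angle forward model on the recipe's angle grid
#' with the supplied ground-truth parameters, applies multiplicative
#' Gaussian noise per repeat, and returns per-angle means and standard
#' deviations. Deterministic under a fixed recipe seed. The generating
#' parameters are stored in the `truth` attribute.
#'
#' @param recipe An [power_angle_recipe()].
#' @param w0 True beam waist, um.
#' @param theta_max_deg True angle of acceptance, degrees.
#' @param k0 Wavenumber, 1/um (default `2 pi / 1.3`, a 1300 nm source).
#' @param tau_mag Splitter-factor magnitude.
#' @return An [power_angle_dataset()] with attribute `truth`.
#' @export
generate_power_angle <- function(recipe = power_angle_recipe(),
                                 w0 = 14.15, theta_max_deg = 1.5709,
                                 k0 = 2 * pi / 1.3, tau_mag = 1) {
  stopifnot(identical(recipe$kind, "power_angle"))
  model <- power_angle_model(recipe$angles_deg, w0, theta_max_deg, k0,
    tau_mag = tau_mag)
  set.seed(recipe$seed)
  reps <- matrix(model, nrow = length(model), ncol = recipe$repeats)
  if (recipe$noise_rel > 0) {
    reps <- reps * (1 + matrix(
      rnorm(length(reps), sd = recipe$noise_rel), nrow = nrow(reps)))
  }
  reps[reps < 0] <- 0
  out <- power_angle_dataset(
    recipe$angles_deg,
    power = rowMeans(reps),
    sd = apply(reps, 1L, function(v) if (length(v) > 1L) sd(v) else 0),
    repeats = recipe$repeats
  )
  attr(out, "truth") <- list(w0 = w0, theta_max_deg = theta_max_deg, k0 = k0,
    tau_mag = tau_mag)
  out
}

#' Recipe for a synthetic through-focus B-scan series
#'
#' Defaults emulate the motorized-stage experiment: a mirror transported
#' through the focus in 11 steps, or a coverglass (refractive index 1.5088)
#' in 7 steps, both at a tilt of about 2.75 degrees, with a 700-point sweep
#' spectrum and additive Gaussian noise on the detected signal. Lateral
#' sampling uses a 9.8 um pixel. The coverglass recipe uses a wider B-scan
#' (64 A-scans) because the tilt estimate averages peak-position jitter
#' across the lateral span; a mirror B-scan with its single clean peak
#' needs only a few.
#'
#' @param kind `"mirror"` or `"coverglass"`.
#' @param stage_positions_um Surface positions of the stage sweep; defaults
#'   to 11 (mirror) or 7 (coverglass) positions centred on the
#'   focus-coincidence position.
#' @param n_ascans A-scans per B-scan.
#' @param lateral_step_um Lateral pixel, um.
#' @param tilt_deg Sample tilt, degrees.
#' @param n1,thickness_um Coverglass index and thickness.
#' @param noise_rel Additive noise sd relative to the series peak signal.
#' @param seed Integer seed.
#' @return List of class `oct_recipe`.
#' @export
focus_series_recipe <- function(kind = c("mirror", "coverglass"),
                                stage_positions_um = NULL,
                                n_ascans = NULL, lateral_step_um = 9.8,
                                tilt_deg = 2.75, n1 = 1.5088,
                                thickness_um = 150, noise_rel = 0.02,
                                seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(stage_positions_um)) {
    stage_positions_um <- if (kind == "mirror") {
      seq(-400, 400, length.out = 11L)
    } else {
      seq(-360, 360, length.out = 7L)
    }
  }
  if (is.null(n_ascans)) n_ascans <- if (kind == "mirror") 8L else 64L
  if (noise_rel < 0) stop("noise_rel must be >= 0", call. = FALSE)
  structure(
    list(kind = kind, stage_positions_um = stage_positions_um,
      n_ascans = as.integer(n_ascans), lateral_step_um = lateral_step_um,
      tilt_deg = tilt_deg, n1 = n1, thickness_um = thickness_um,
      noise_rel = noise_rel, seed = as.integer(seed)),
    class = "oct_recipe"
  )
}

#' Generate a synthetic through-focus B-scan series
#'
#' Simulates one B-scan per stage position, shifting the sample surface
#' along the depth axis, then adds seeded Gaussian noise (standard deviation
#' `noise_rel` times the peak |signal| of the whole series). Stage positions
#' are surface depths on the beam axis; the focus-coincidence position
#' (where the reflected beam refocuses at the detector reference point) is
#' recorded in the returned ground truth.
#'
#' @param recipe An [focus_series_recipe()].
#' @param beam,geometry,grid Forward-model configuration; defaults match the
#'   calibrated instrument (waist 14.15 um, acceptance 1.5709 deg, 700-point
#'   sweep).
#' @param n_nodes Quadrature nodes per axis for the acceptance integral.
#' @return List of class `oct_focus_series`: `bscans` (list of
#'   [simulate_bscan()] results), `stage_um`, `truth` (tilt, thickness,
#'   focus-coincidence position, reference-mirror position, per-stage exact
#'   surface depths).
#' @export
generate_focus_series <- function(recipe = focus_series_recipe(),
                                  beam = beam_parameters(14.15),
                                  geometry = system_geometry(),
                                  grid = wavenumber_grid(4.7835, 4.8973),
                                  n_nodes = 32L) {
  stopifnot(recipe$kind %in% c("mirror", "coverglass"))
  x1 <- (seq_len(recipe$n_ascans) - (recipe$n_ascans + 1) / 2) *
    recipe$lateral_step_um
  sample_of <- function(x3) {
    if (recipe$kind == "mirror") {
      layered_sample("mirror", tilt_deg = recipe$tilt_deg,
        surface_x3_um = x3)
    } else {
      layered_sample("slab", tilt_deg = recipe$tilt_deg, n1 = recipe$n1,
        thickness_um = recipe$thickness_um, surface_x3_um = x3)
    }
  }
  bscans <- lapply(recipe$stage_positions_um, function(x3) {
    simulate_bscan(sample_of(x3), beam, geometry, grid, x1,
      n_nodes = n_nodes)
  })
  set.seed(recipe$seed)
  if (recipe$noise_rel > 0) {
    peak <- max(vapply(bscans, function(b) max(abs(b$signals)), numeric(1)))
    bscans <- lapply(bscans, function(b) {
      b$signals <- b$signals +
        matrix(rnorm(length(b$signals), sd = recipe$noise_rel * peak),
          nrow = nrow(b$signals))
      b
    })
  }
  nu3 <- cos(deg2rad(recipe$tilt_deg))
  cos_t <- if (recipe$kind == "coverglass") {
    Re(fresnel_interface(1, recipe$n1,
      cos(deg2rad(recipe$tilt_deg)))$cos_theta_t)
  } else {
    NA_real_
  }
  structure(
    list(
      bscans = bscans, stage_um = recipe$stage_positions_um,
      truth = list(
        kind = recipe$kind, tilt_deg = recipe$tilt_deg,
        thickness_um = if (recipe$kind == "coverglass") recipe$thickness_um else NA_real_,
        n1 = if (recipe$kind == "coverglass") recipe$n1 else NA_real_,
        cos_theta_t = cos_t,
        focus_position_um = beam$r0 / (2 * nu3^2),
        xM3_um = geometry$xM3,
        surface_x3_um = lapply(bscans, function(b) b$surface_x3_um)
      )
    ),
    class = "oct_focus_series"
  )
}

#' @export
print.oct_focus_series <- function(x, ...) {
  cat(sprintf(
    "through-focus series (%s): %d stage positions, %d A-scans each\n",
    x$truth$kind, length(x$bscans), ncol(x$bscans[[1]]$signals)
  ))
  invisible(x)
}
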
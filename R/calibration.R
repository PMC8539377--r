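#' Power-versus-angle forward model
#'
#' Detected power of the light back-reflected by a mirror tilted by
#' `theta_Omega`, as a function of the beam waist `w0` and the angle of
#' acceptance `theta_max`. The calibration geometry puts the mirror surface
#' through the goniometer pivot at the beam focus (`r0 = x_Omega3`, both 0
#' by default), and approximates the acceptance set by its rectangle, giving
#'
#' `G = |tau|^2 |I1 * I2 / (4 pi^2)|^2`
#'
#' with the two truncated-Gaussian line integrals
#' `I1 = int exp(-psi2 k1^2 - i psi1 k1) dk1` over
#' `[-L1 - k0 sin(2 theta), L1 - k0 sin(2 theta)]` and
#' `I2 = int exp(-psi2 k2^2) dk2` over `[-L2, L2]`. Both are evaluated in
#' closed form through the (complex) error function; `method = "quadrature"`
#' instead integrates the same rectangle by Gauss-Legendre quadrature and is
#' used as the internal cross-check.
#'
#' @param theta_deg Mirror tilt(s), degrees (vectorized).
#' @param w0 Beam waist, micrometres (> 0).
#' @param theta_max_deg Angle of acceptance, degrees, in (0, 90).
#' @param k0 Wavenumber, 1/um.
#' @param tau_mag Magnitude of the splitter/loss factor.
#' @param r0 Focus position, micrometres (default 0: pivot-aligned setup).
#' @param x_omega3 Surface position, micrometres (default equal to `r0`).
#' @param method `"erf"` (closed form) or `"quadrature"`.
#' @param n_nodes Per-axis node count for `method = "quadrature"`.
#' @return Nonnegative model power for each angle.
#' @export
power_angle_model <- function(theta_deg, w0, theta_max_deg, k0, tau_mag = 1,
                              r0 = 0, x_omega3 = r0,
                              method = c("erf", "quadrature"),
                              n_nodes = 160L) {
  method <- match.arg(method)
  if (w0 <= 0) stop("w0 must be positive", call. = FALSE)
  if (theta_max_deg <= 0 || theta_max_deg >= 90) {
    stop("theta_max_deg must lie in (0, 90)", call. = FALSE)
  }
  a <- w0^2 / 4
  th <- deg2rad(theta_deg)
  th_max <- deg2rad(theta_max_deg)
  cth <- cos(th)
  psi2 <- a + 1i * (cth^2 * x_omega3 - r0 / 2) / k0
  psi1 <- sin(2 * th) * x_omega3
  cc <- k0 * sin(2 * th)
  L1 <- k0 * (-sin(2 * th - th_max) + sin(2 * th))
  L2 <- k0 * sin(th_max)
  if (method == "erf") {
    I2 <- gauss_segment_integral(psi2[1], 0, -L2, L2)
    # psi2, psi1 vary with theta when the surface is displaced; loop stays
    # cheap because the erf path is vectorized over the angle-dependent limits
    I1 <- vapply(seq_along(th), function(i) {
      gauss_segment_integral(psi2[i], psi1[i], -L1[i] - cc[i], L1[i] - cc[i])
    }, complex(1))
    if (x_omega3 != 0 || r0 != 0) {
      I2 <- vapply(seq_along(th), function(i) {
        gauss_segment_integral(psi2[i], 0, -L2, L2)
      }, complex(1))
    }
    tau_mag^2 * Mod(I1 * I2 / (4 * pi^2))^2
  } else {
    vapply(seq_along(th), function(i) {
      f <- function(k1, k2) {
        exp(-psi2[i] * (k1^2 + k2^2) - 1i * psi1[i] * k1)
      }
      val <- gl_quad2d(f, c(-L1[i] - cc[i], L1[i] - cc[i]), c(-L2, L2),
        n_nodes)
      tau_mag^2 * Mod(val / (4 * pi^2))^2
    }, numeric(1))
  }
}

#' Power-versus-angle dataset container
#'
#' @param angles_deg Strictly increasing tilt angles, degrees.
#' @param power Mean measured power per angle (>= 0).
#' @param sd Optional per-angle standard deviation.
#' @param repeats Number of repeats averaged per angle.
#' @return Object of class `oct_power_angle` (a data.frame with attributes).
#' @export
power_angle_dataset <- function(angles_deg, power, sd = NULL, repeats = 1L) {
  if (is.unsorted(angles_deg, strictly = TRUE)) {
    stop("angles must be strictly increasing", call. = FALSE)
  }
  if (length(power) != length(angles_deg)) {
    stop("power and angles lengths differ", call. = FALSE)
  }
  if (any(power < 0)) stop("powers must be >= 0", call. = FALSE)
  out <- data.frame(angle_deg = angles_deg, power = power,
    sd = if (is.null(sd)) NA_real_ else sd)
  attr(out, "repeats") <- as.integer(repeats)
  class(out) <- c("oct_power_angle", "data.frame")
  out
}

#' Least-squares extraction of beam waist and acceptance angle
#'
#' Fits the power-versus-angle forward model to a dataset by minimizing the
#' mean squared residual over `(w0, theta_max)`. The overall scale (the
#' unknown `|tau|^2`) is profiled out analytically at every candidate (it
#' enters linearly). Because the objective surface can be multimodal, the
#' fit runs a deterministic two-stage search: a log-spaced global grid over
#' `init_box`, followed by Nelder-Mead refinement in log-parameters from the
#' best grid point. No randomness is involved.
#'
#' @param data An [power_angle_dataset()] (or data.frame with `angle_deg`,
#'   `power`).
#' @param k0 Wavenumber used for the sweep, 1/um.
#' @param init_box List with ranges `w0` (um) and `theta_max_deg` (deg).
#' @param grid_n Per-axis global grid size.
#' @param ... Passed to [power_angle_model()] (e.g. `r0`).
#' @return List of class `oct_fit`: `w0`, `theta_max_deg`, `scale`,
#'   `objective`, `grid_best` (the global-stage optimum), `convergence`,
#'   `fitted`, `residuals`.
#' @export
fit_beam_parameters <- function(data, k0,
                                init_box = list(w0 = c(4, 50),
                                  theta_max_deg = c(0.2, 6)),
                                grid_n = c(32L, 32L), ...) {
  angles <- data$angle_deg
  power <- data$power
  if (length(unique(angles)) < 5L) {
    stop("need at least 5 distinct angles spanning the peak", call. = FALSE)
  }
  if (var(power) < .Machine$double.eps * max(power, 1)^2) {
    stop("degenerate flat power data: parameters not identifiable", call. = FALSE)
  }
  objective <- function(w0, th_max) {
    m <- power_angle_model(angles, w0, th_max, k0, ...)
    s <- sum(power * m) / sum(m^2)
    if (!is.finite(s) || s <= 0) return(list(obj = Inf, scale = NA_real_))
    list(obj = mean((power - s * m)^2), scale = s)
  }
  w0s <- exp(seq(log(init_box$w0[1]), log(init_box$w0[2]),
    length.out = grid_n[1]))
  ths <- exp(seq(log(init_box$theta_max_deg[1]),
    log(init_box$theta_max_deg[2]), length.out = grid_n[2]))
  grid_obj <- matrix(Inf, grid_n[1], grid_n[2])
  for (i in seq_along(w0s)) {
    for (j in seq_along(ths)) {
      grid_obj[i, j] <- objective(w0s[i], ths[j])$obj
    }
  }
  best <- arrayInd(which.min(grid_obj), dim(grid_obj))
  grid_best <- list(w0 = w0s[best[1]], theta_max_deg = ths[best[2]],
    objective = min(grid_obj))
  fn <- function(par) objective(exp(par[1]), exp(par[2]))$obj
  opt <- optim(log(c(grid_best$w0, grid_best$theta_max_deg)), fn,
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 2000L))
  # one restart from the polished point guards against premature simplex
  # collapse on narrow valleys
  opt2 <- optim(opt$par, fn, method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 2000L))
  if (opt2$value < opt$value) opt <- opt2
  w0_hat <- exp(opt$par[1])
  th_hat <- exp(opt$par[2])
  ob <- objective(w0_hat, th_hat)
  m <- power_angle_model(angles, w0_hat, th_hat, k0, ...)
  structure(
    list(
      w0 = w0_hat, theta_max_deg = th_hat, scale = ob$scale,
      objective = ob$obj, grid_best = grid_best,
      convergence = opt$convergence, n_obs = length(angles),
      fitted = ob$scale * m, residuals = power - ob$scale * m
    ),
    class = "oct_fit"
  )
}

#' @export
print.oct_fit <- function(x, ...) {
  cat(sprintf(
    "beam-parameter fit: w0 = %.4f um, theta_max = %.4f deg (rms residual %.3g, n = %d)\n",
    x$w0, x$theta_max_deg, sqrt(x$objective), x$n_obs
  ))
  invisible(x)
}
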
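#' Band-limited depth intensity of an A-scan
#'
#' Squared modulus of the band-limited Fourier transform of the spectrum,
#' `I(kappa) = (1/2 pi) | int_kmin^kmax M(k0) exp(-i k0 kappa) dk0 |^2`
#' (symmetric transform convention), evaluated by trapezoid quadrature.
#' With `kappa = NULL` the transform is computed on the zero-padded FFT
#' grid, whose spacing (`2 pi / (pad_factor * n * dk)`) is the axial pixel
#' size; zero-padding refines the kappa sampling in the usual way. A real
#' input spectrum gives `I(kappa) = I(-kappa)`.
#'
#' @param ascan An [simulate_ascan()] result, or any list with fields
#'   `grid` ([wavenumber_grid()]) and `signal`.
#' @param kappa Optional explicit kappa grid (um); default: zero-padded FFT
#'   grid over both signs.
#' @param pad_factor Zero-padding factor for the FFT route (default 8).
#' @return Object of class `oct_depth_spectrum`: list with `kappa`,
#'   `intensity`, `pixel` (kappa spacing of the FFT route) and `grid`.
#' @export
depth_intensity <- function(ascan, kappa = NULL, pad_factor = 8L) {
  grid <- ascan$grid
  M2 <- ascan$signal
  stop_if_not_finite(M2, "A-scan signal")
  if (length(M2) != grid$n) stop("signal length must match grid", call. = FALSE)
  dk <- grid$k[2] - grid$k[1]
  w <- rep(dk, grid$n)
  w[c(1L, grid$n)] <- dk / 2
  if (is.null(kappa)) {
    N <- as.integer(pad_factor) * grid$n
    padded <- c(w * M2, rep(0, N - grid$n))
    A <- fft(padded)
    m <- seq_len(N) - 1L
    kap <- 2 * pi * m / (N * dk)
    neg <- kap > pi / dk
    kap[neg] <- kap[neg] - 2 * pi / dk
    # carrier phase from kmin does not change |A|
    ord <- order(kap)
    structure(
      list(kappa = kap[ord], intensity = Mod(A[ord])^2 / (2 * pi),
        pixel = 2 * pi / (N * dk), grid = grid),
      class = "oct_depth_spectrum"
    )
  } else {
    A <- vapply(kappa, function(kp) sum(w * M2 * exp(-1i * grid$k * kp)),
      complex(1))
    structure(
      list(kappa = kappa, intensity = Mod(A)^2 / (2 * pi),
        pixel = if (length(kappa) > 1L) min(diff(sort(kappa))) else NA_real_,
        grid = grid),
      class = "oct_depth_spectrum"
    )
  }
}

#' @export
print.oct_depth_spectrum <- function(x, ...) {
  cat(sprintf(
    "depth spectrum: %d kappa samples in [%g, %g] um, pixel %.3g um\n",
    length(x$kappa), min(x$kappa), max(x$kappa), x$pixel
  ))
  invisible(x)
}

#' Locate depth peaks in a depth spectrum
#'
#' Finds the `n_peaks` strongest local maxima of `I(kappa)` on the positive
#' kappa half-line (the negative-side twin of a real spectrum is redundant),
#' excluding a DC guard band around the origin. Each peak position is
#' refined below the grid by a local quadratic (three-point parabola)
#' interpolation. After a peak is accepted, a guard interval of two sinc
#' main lobes (`2 pi / delta`) around it is masked before searching for the
#' next.
#'
#' @param spectrum An [depth_intensity()] result.
#' @param exclusion_halfwidth DC guard half-width in um; default 5 kappa
#'   pixels.
#' @param n_peaks Number of peaks to return.
#' @return Data frame with columns `Theta0` (um) and `height`, strongest
#'   first.
#' @export
locate_peak <- function(spectrum, exclusion_halfwidth = NULL, n_peaks = 1L) {
  kap <- spectrum$kappa
  I <- spectrum$intensity
  if (all(I == 0)) stop("spectrum is identically zero: no peak", call. = FALSE)
  if (is.null(exclusion_halfwidth)) exclusion_halfwidth <- 5 * spectrum$pixel
  usable <- kap > exclusion_halfwidth
  if (!any(usable)) stop("no kappa samples beyond the DC exclusion", call. = FALSE)
  guard <- 2 * pi / spectrum$grid$delta
  out <- data.frame(Theta0 = numeric(0), height = numeric(0))
  masked <- !usable
  for (p in seq_len(n_peaks)) {
    Iw <- I
    Iw[masked] <- -Inf
    i0 <- which.max(Iw)
    if (!is.finite(Iw[i0]) || Iw[i0] <= 0) {
      stop("no peak above the noise floor", call. = FALSE)
    }
    th <- kap[i0]
    if (i0 > 1L && i0 < length(kap) && !masked[i0 - 1L] && !masked[i0 + 1L]) {
      dkap <- kap[i0 + 1L] - kap[i0]
      denom <- I[i0 - 1L] - 2 * I[i0] + I[i0 + 1L]
      if (denom < 0) {
        th <- kap[i0] + 0.5 * dkap * (I[i0 - 1L] - I[i0 + 1L]) / denom
      }
    }
    out <- rbind(out, data.frame(Theta0 = th, height = I[i0]))
    masked <- masked | abs(kap - th) < guard
  }
  out
}

#' Two-sinc surrogate of the reduced-model depth transform
#'
#' Band-limited transform of the reduced measurement model in the
#' small-`sigma` regime (`sigma` of order `1/kbar`, both much smaller than
#' `1/delta`): a pair of sinc kernels centred at `+-Theta0`,
#' `K delta / sqrt(2 pi) exp(-kbar^2 sigma^2) kbar^2 *
#'  (si(delta (kappa - Theta0)) exp(-i kbar (kappa + Theta0)) +
#'   si(delta (kappa + Theta0)) exp(-i kbar (kappa - Theta0)))`.
#' Warns when the regime assumption `sigma << 1/delta` is violated.
#'
#' @param params [reduced_model_params()] list.
#' @param kappa Kappa value(s), um.
#' @param grid An [wavenumber_grid()] supplying `kbar` and `delta`.
#' @return Complex transform values; `Mod(.)^2` is the surrogate intensity.
#' @export
reduced_model_transform <- function(params, kappa, grid) {
  stopifnot(inherits(grid, "oct_kgrid"))
  if (params$sigma > 0.2 * grid$sigma_delta) {
    warning("regime assumption sigma << 1/delta violated; surrogate may be inaccurate")
  }
  kb <- grid$kbar
  dl <- grid$delta
  th <- params$Theta0
  params$K * dl / sqrt(2 * pi) * exp(-kb^2 * params$sigma^2) * kb^2 *
    (si(dl * (kappa - th)) * exp(-1i * kb * (kappa + th)) +
      si(dl * (kappa + th)) * exp(-1i * kb * (kappa - th)))
}

#' Surrogate peak intensity of the reduced model
#'
#' Closed form of the depth intensity at its maximum `kappa = Theta0` in the
#' two-sinc regime:
#' `K^2 delta^2/(2 pi) exp(-2 kbar^2 sigma^2) kbar^4 *
#'  (1 + si(2 delta Theta0)^2 + 2 si(2 delta Theta0) cos(2 kbar Theta0))`.
#'
#' @inheritParams reduced_model_transform
#' @return Nonnegative intensity value.
#' @export
reduced_model_peak_intensity <- function(params, grid) {
  kb <- grid$kbar
  dl <- grid$delta
  th <- params$Theta0
  s2 <- si(2 * dl * th)
  params$K^2 * dl^2 / (2 * pi) * exp(-2 * kb^2 * params$sigma^2) * kb^4 *
    (1 + s2^2 + 2 * s2 * cos(2 * kb * th))
}

#' Estimate the surface tilt from a B-scan
#'
#' Converts the located peak of every A-scan to a depth through the
#' small-tilt factor-2 relation (`depth = Theta0 / 2`), fits a line of depth
#' against lateral position, and returns the tilt as
#' `atan(d depth / d x1)` — the slope form consistent with the surface
#' normal parameterization `(sin(theta), 0, cos(theta))`.
#'
#' @param bscan An [simulate_bscan()] result (or a list with `grid`,
#'   `signals`, `x1_um`).
#' @param peak_depths Optional per-A-scan `Theta0` values (um); located via
#'   [locate_peak()] when omitted.
#' @param ... Passed to [depth_intensity()] / [locate_peak()].
#' @return List with `tilt_deg`, `slope`, `depths_um` (per A-scan
#'   `Theta0/2`), `x1_um`.
#' @export
estimate_tilt <- function(bscan, peak_depths = NULL, ...) {
  x1 <- bscan$x1_um
  if (is.null(peak_depths)) {
    peak_depths <- vapply(seq_along(x1), function(i) {
      a <- list(grid = bscan$grid, signal = bscan$signals[, i])
      sp <- depth_intensity(a, ...)
      locate_peak(sp)$Theta0[1]
    }, numeric(1))
  }
  if (length(x1) < 2L) stop("need at least two A-scans", call. = FALSE)
  if (length(unique(x1)) < 2L) stop("lateral positions are collinear", call. = FALSE)
  depths <- peak_depths / 2
  fit <- lm(depths ~ x1)
  slope <- unname(coef(fit)[2])
  list(tilt_deg = rad2deg(atan(slope)), slope = slope,
    depths_um = depths, x1_um = x1)
}

#' Slab thickness from a two-peak A-scan
#'
#' Inverts the slab round-trip phase `2 k0 n1 d cos(theta_t)`: with the
#' front- and back-surface peaks at `Theta0_front < Theta0_back`,
#' `d = (Theta0_back - Theta0_front) / (2 n1 cos(theta_t))`.
#'
#' @param theta0_front,theta0_back Located peak positions, um.
#' @param n1 Slab refractive index (> 1 for a physical slab; 1 gives half
#'   the raw separation).
#' @param cos_theta_t Transmission-angle cosine (default 1, normal
#'   incidence).
#' @return Thickness in micrometres.
#' @export
estimate_thickness <- function(theta0_front, theta0_back, n1,
                               cos_theta_t = 1) {
  if (n1 < 1) stop("n1 must be >= 1", call. = FALSE)
  if (any(theta0_back <= theta0_front)) {
    stop("peaks must be ordered: theta0_back > theta0_front", call. = FALSE)
  }
  (theta0_back - theta0_front) / (2 * n1 * cos_theta_t)
}

#' Mean-of-max focus statistic over a through-focus series
#'
#' For every B-scan of a stage series, computes the maximum depth intensity
#' of each A-scan (beyond the DC exclusion) and summarizes it as mean and
#' standard deviation over the A-scans; the series of means is then
#' normalized to its own maximum, mirroring how experimental and simulated
#' through-focus curves are compared.
#'
#' @param bscans List of B-scans (one per stage position).
#' @param stage_um Optional stage positions for labelling.
#' @param ... Passed to [depth_intensity()] / [locate_peak()].
#' @return Data frame with `stage_um`, `mean` (normalized), `sd` (same
#'   scale), `mean_raw`, `sd_raw`, `n_ascans`.
#' @export
bscan_focus_statistic <- function(bscans, stage_um = NULL, ...) {
  if (length(bscans) == 0L) stop("empty B-scan series", call. = FALSE)
  per_scan <- lapply(bscans, function(b) {
    if (ncol(b$signals) == 0L) stop("empty B-scan", call. = FALSE)
    vapply(seq_len(ncol(b$signals)), function(i) {
      a <- list(grid = b$grid, signal = b$signals[, i])
      sp <- depth_intensity(a, ...)
      locate_peak(sp)$height[1]
    }, numeric(1))
  })
  mean_raw <- vapply(per_scan, mean, numeric(1))
  sd_raw <- vapply(per_scan, function(v) if (length(v) > 1L) sd(v) else 0,
    numeric(1))
  scale <- max(mean_raw)
  data.frame(
    stage_um = if (is.null(stage_um)) seq_along(bscans) else stage_um,
    mean = mean_raw / scale, sd = sd_raw / scale,
    mean_raw = mean_raw, sd_raw = sd_raw,
    n_ascans = vapply(per_scan, length, integer(1))
  )
}
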
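test_that("depth intensity: null input, symmetry, scaling and Parseval identity", {
  grid <- sweep_grid()
  zero <- list(grid = grid, signal = rep(0, grid$n))
  expect_true(all(depth_intensity(zero)$intensity == 0))
  p <- reduced_model_params(K = 1, sigma = 0.2753, Theta0 = 350)
  a <- list(grid = grid, signal = reduced_model(p, grid$k))
  kap <- seq(-500, 500, by = 2.5)
  sp <- depth_intensity(a, kappa = kap)
  expect_equal(sp$intensity, rev(sp$intensity), tolerance = 1e-12)
  # peak position invariant under positive rescaling of the A-scan
  sp1 <- depth_intensity(a)
  a2 <- list(grid = grid, signal = 7.3 * a$signal)
  sp2 <- depth_intensity(a2)
  expect_equal(locate_peak(sp1)$Theta0, locate_peak(sp2)$Theta0)
  expect_equal(sp2$intensity, 7.3^2 * sp1$intensity, tolerance = 1e-12)
  # discrete Parseval identity for the zero-padded transform
  dk <- grid$k[2] - grid$k[1]
  w <- rep(dk, grid$n)
  w[c(1, grid$n)] <- dk / 2
  lhs <- sum(sp1$intensity) * sp1$pixel
  rhs <- sum((w * a$signal)^2) / dk
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("a pure cosine spectrum peaks at its delay", {
  grid <- sweep_grid()
  a <- list(grid = grid, signal = cos(grid$k * 350))
  sp <- depth_intensity(a)
  pk <- locate_peak(sp)
  expect_lt(abs(pk$Theta0 - 350), sp$pixel)
})

test_that("reduced-model peaks are located within one zero-padded pixel", {
  grid <- sweep_grid()
  for (Th in c(100, 225, 350, 475, 600)) {
    p <- reduced_model_params(K = 1, sigma = 0.2753, Theta0 = Th)
    a <- list(grid = grid, signal = reduced_model(p, grid$k))
    sp <- depth_intensity(a)
    expect_lt(abs(locate_peak(sp)$Theta0 - Th), sp$pixel)
  }
})

test_that("two well-separated surfaces give two recoverable peaks", {
  grid <- sweep_grid()
  sig <- reduced_model(reduced_model_params(1, 0.2753, 400), grid$k) +
    0.8 * reduced_model(reduced_model_params(1, 0.2753, 850), grid$k)
  sp <- depth_intensity(list(grid = grid, signal = sig))
  pk <- locate_peak(sp, n_peaks = 2)
  expect_equal(sort(pk$Theta0), c(400, 850), tolerance = 2 * sp$pixel / 400)
})

test_that("DC energy is excluded from the peak search", {
  grid <- sweep_grid()
  # an uncompensated offset of the order of the signal amplitude (larger
  # offsets are removed by background subtraction before analysis)
  sig <- 2 + reduced_model(reduced_model_params(1, 0.2753, 350), grid$k)
  sp <- depth_intensity(list(grid = grid, signal = sig))
  expect_lt(abs(locate_peak(sp)$Theta0 - 350), sp$pixel)
  expect_error(locate_peak(depth_intensity(
    list(grid = grid, signal = rep(0, grid$n)))), "zero")
})

test_that("two-sinc surrogate reproduces its squared three-term expansion", {
  grid <- sweep_grid()
  p <- reduced_model_params(K = 1.7, sigma = 0.2753, Theta0 = 350)
  kap <- seq(300, 400, by = 0.5)
  Fv <- reduced_model_transform(p, kap, grid)
  s1 <- si_t(grid$delta * (kap - 350))
  s2 <- si_t(grid$delta * (kap + 350))
  expanded <- p$K^2 * grid$delta^2 / (2 * pi) *
    exp(-2 * grid$kbar^2 * p$sigma^2) * grid$kbar^4 *
    (s1^2 + s2^2 + 2 * s1 * s2 * cos(2 * grid$kbar * 350))
  expect_equal(Mod(Fv)^2, expanded, tolerance = 1e-12)
  # regime constants: sigma*kbar of order one, sigma << 1/delta
  Q <- grid$sigma_kbar / p$sigma
  expect_gt(Q, 0.5)
  expect_lt(Q, 1.5)
  expect_lt(p$sigma / grid$sigma_delta, 0.1)
})

test_that("surrogate peak intensity matches direct quadrature in the sinc regime", {
  grid <- sweep_grid()
  for (Th in c(225, 350, 475)) {
    p <- reduced_model_params(K = 1, sigma = 0.2753, Theta0 = Th)
    a <- list(grid = grid, signal = reduced_model(p, grid$k))
    est <- locate_peak(depth_intensity(a))$Theta0
    direct <- depth_intensity(a, kappa = est)$intensity
    expect_equal(reduced_model_peak_intensity(p, grid) / direct, 1,
      tolerance = 0.1)
  }
})

# cheap synthetic B-scan built directly from the reduced model
reduced_bscan <- function(tilt_deg, x1, xM3 = 700, x3c = -100) {
  grid <- sweep_grid()
  depths <- x3c - tan(deg2rad_t(tilt_deg)) * x1
  sigs <- vapply(depths, function(x3) {
    reduced_model(reduced_model_params(1, 0.2753, 2 * (xM3 - x3)), grid$k)
  }, numeric(grid$n))
  structure(list(grid = grid, x1_um = x1, signals = sigs,
    surface_x3_um = depths), class = "oct_bscan")
}

test_that("tilt estimation: level surface, sign antisymmetry and recovery", {
  x1 <- seq(-150, 150, by = 25)
  flat <- reduced_bscan(0, x1)
  expect_equal(estimate_tilt(flat)$tilt_deg, 0, tolerance = 1e-6)
  up <- estimate_tilt(reduced_bscan(2.75, x1))
  dn <- estimate_tilt(reduced_bscan(-2.75, x1))
  expect_equal(up$tilt_deg, -dn$tilt_deg, tolerance = 1e-6)
  expect_equal(up$tilt_deg, 2.75, tolerance = 0.05)
  expect_error(estimate_tilt(reduced_bscan(1, c(0, 0))), "collinear")
})

test_that("thickness inversion divides the peak separation by the optical factor", {
  expect_equal(estimate_thickness(400, 500, 1, 1), 50)
  ct <- Re(fresnel_interface(1, 1.5088, cos(deg2rad_t(2.75)))$cos_theta_t)
  expect_equal(estimate_thickness(400, 400 + 2 * 1.5088 * 150 * ct,
    1.5088, ct), 150, tolerance = 1e-12)
  expect_error(estimate_thickness(500, 400, 1.5), "ordered")
})

test_that("doubling the slab thickness doubles the measured peak separation", {
  grid <- sweep_grid()
  geo <- system_geometry(xM3_um = 700)
  beam <- table_beam()
  # thicknesses several axial resolution cells apart, so the two sinc
  # kernels overlap only through their sidelobes
  sep <- vapply(c(150, 300), function(d) {
    s <- layered_sample("slab", tilt_deg = 0.5, n1 = 1.5088,
      thickness_um = d, surface_x3_um = -100)
    a <- simulate_ascan(s, beam, geo, grid)
    pk <- locate_peak(depth_intensity(a), n_peaks = 2)
    diff(sort(pk$Theta0))
  }, numeric(1))
  expect_equal(sep[2] / sep[1], 2, tolerance = 0.02)
  ct <- Re(fresnel_interface(1, 1.5088, cos(deg2rad_t(0.5)))$cos_theta_t)
  expect_equal(sep[1], 2 * 1.5088 * 150 * ct, tolerance = 0.02)
})

test_that("focus statistic is order-invariant and has zero spread for clones", {
  grid <- sweep_grid(128L)
  sig <- reduced_model(reduced_model_params(1, 0.2753, 350), grid$k)
  b <- structure(list(grid = grid, x1_um = c(-10, 0, 10),
    signals = cbind(sig, sig, sig), surface_x3_um = rep(0, 3)),
    class = "oct_bscan")
  st <- bscan_focus_statistic(list(b))
  expect_equal(st$sd, 0)
  expect_equal(st$mean, 1)
  b2 <- b
  b2$signals <- b$signals[, c(2, 3, 1)]
  expect_equal(bscan_focus_statistic(list(b2))$mean_raw, st$mean_raw)
})
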
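test_that("acceptance membership reduces to a disk for an untilted surface", {
  k0 <- 4.8404
  B <- acceptance_set(1.5709, c(0, 0, 1), k0)
  set.seed(11)
  k1 <- runif(200, -0.5, 0.5)
  k2 <- runif(200, -0.5, 0.5)
  expect_equal(
    acceptance_contains(B, k1, k2),
    k1^2 + k2^2 <= k0^2 * sin(deg2rad_t(1.5709))^2
  )
  # 90 degrees accepts every propagating component
  Ball <- acceptance_set(90, c(0, 0, 1), k0)
  expect_true(all(acceptance_contains(Ball, k1, k2)))
  # untilted rectangle is [-k0 sin, k0 sin]^2
  expect_equal(B$center_k1, 0)
  expect_equal(B$L1, k0 * sin(deg2rad_t(1.5709)))
  expect_equal(B$L2, k0 * sin(deg2rad_t(1.5709)))
})

test_that("rectangle circumscribes the exact acceptance set (area ratio near 4/pi)", {
  k0 <- 4.8404
  B <- acceptance_set(1.5709, tilted_normal(2.75), k0)
  # dense-grid membership oracle over the rectangle's bounding box
  k1g <- seq(B$center_k1 - 2 * B$L1, B$center_k1 + 2 * B$L1,
    length.out = 601L)
  k2g <- seq(-2 * B$L2, 2 * B$L2, length.out = 601L)
  cnt <- 0
  for (k2 in k2g) {
    cnt <- cnt + sum(acceptance_contains(B, k1g, rep(k2, length(k1g))))
  }
  area_exact <- cnt * diff(k1g[1:2]) * diff(k2g[1:2])
  area_rect <- 4 * B$L1 * B$L2
  # the exact set is nearly the disk inscribed in the rectangle
  expect_equal(area_rect / area_exact, 4 / pi, tolerance = 0.02)
})

test_that("closed-form surface field equals the Gaussian-integral quadrature", {
  k0 <- 4.8404
  worst <- 0
  for (tilt in c(0, 1.1, 2.75)) {
    for (x3 in c(-500, -150, 0, 150, 500)) {
      for (r0 in c(0, -300)) {
        beam <- beam_parameters(14.15, r0_um = r0)
        nu <- tilted_normal(tilt)
        cf <- closed_form_surface_field(beam, k0, nu, x3, -0.2)
        pe <- phase_elements(beam, nu, x3, k0)
        rho <- sqrt(37 / beam$a)
        I1 <- gl_sum_1d(function(k) exp(-pe$psi2 * k^2 - 1i * pe$psi1 * k),
          -rho, rho, 500L)
        I2 <- gl_sum_1d(function(k) exp(-pe$psi2 * k^2), -rho, rho, 500L)
        num <- Mod(-0.2 * I1 * I2) / (4 * pi^2)
        worst <- max(worst, abs(num - cf) / cf)
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("closed-form field peaks at focus coincidence and decays with defocus", {
  beam <- table_beam()
  k0 <- 4.8404
  # psi1 = 0 (untilted): strictly decreasing magnitude in |d|
  nu <- c(0, 0, 1)
  mags <- vapply(c(0, 50, 150, 400, 900), function(x3) {
    closed_form_surface_field(beam, k0, nu, x3, 1)
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
  expect_equal(mags[1], 1 / (4 * pi * beam$a), tolerance = 1e-12)
})

test_that("far-field stationary wavevector reflects back into the observation direction", {
  k0 <- 4.8404
  ff <- far_field_wavevector(c(0, 0, 1), c(0, 0, 1), k0)
  expect_equal(ff$c3, -1)
  expect_equal(c(ff$k1, ff$k2), c(0, 0))
  set.seed(5)
  for (i in 1:20) {
    tilt <- runif(1, -10, 10)
    nu <- tilted_normal(tilt)
    v <- rnorm(3)
    s <- v / sqrt(sum(v^2))
    ff <- tryCatch(far_field_wavevector(s, nu, k0), error = function(e) NULL)
    if (is.null(ff) || ff$k1^2 + ff$k2^2 >= k0^2) next
    # the incident component always travels downward (k3 < 0); its
    # specular reflection points along -sign(c3) * s
    k <- c(ff$k1, ff$k2, -sqrt(k0^2 - ff$k1^2 - ff$k2^2))
    kr <- reflect_wavevector(k, nu)
    expect_equal(kr / k0, -sign(ff$c3) * s, tolerance = 1e-10)
  }
  # tilted mirror observed on axis: |k_transverse| = k0 sin(2 theta)
  ff <- far_field_wavevector(c(0, 0, 1), tilted_normal(2.75), k0)
  expect_equal(abs(ff$k1), k0 * sin(2 * deg2rad_t(2.75)), tolerance = 1e-12)
  expect_equal(ff$k2, 0)
  expect_error(
    far_field_wavevector(c(1, 0, 0), c(0, 0, 1), k0),
    "grazing"
  )
})

test_that("far field scales as 1/r and ignores the focus position", {
  beam <- table_beam()
  k0 <- 4.8404
  s <- layered_sample("mirror", surface_x3_um = 0)
  e3 <- c(0, 0, 1)
  v1 <- 1e5 * Mod(scattered_field_far(s, beam, k0, 1e5, e3))
  v2 <- 2e5 * Mod(scattered_field_far(s, beam, k0, 2e5, e3))
  expect_equal(v1, v2, tolerance = 1e-12)
  moved <- beam_parameters(14.15, r0_um = -250)
  expect_equal(
    Mod(scattered_field_far(s, moved, k0, 1e5, e3)),
    Mod(scattered_field_far(s, beam, k0, 1e5, e3)),
    tolerance = 1e-12
  )
})

test_that("near-field quadrature vanishes for a non-reflecting sample", {
  beam <- table_beam()
  k0 <- 4.8404
  none <- layered_sample("interface", n1 = 1)  # index-matched: beta = 0
  expect_equal(
    Mod(scattered_field_near(none, beam, k0, c(0, 0, 100), n_nodes = 32)),
    0
  )
})

test_that("near-field magnitude matches the paraxial closed form at the origin", {
  k0 <- 4.8404
  beam <- beam_parameters(14.15, r0_um = -200)
  s <- layered_sample("mirror", surface_x3_um = -200)
  En <- scattered_field_near(s, beam, k0, c(0, 0, 0))
  cf <- closed_form_surface_field(beam, k0, s$normal, -200, 1)
  expect_equal(Mod(En), cf, tolerance = 1e-3)
})

test_that("restricting the acceptance set can only reduce a nonnegative integrand", {
  k0 <- 4.8404
  beam <- beam_parameters(14.15, r0_um = 0)
  s <- layered_sample("mirror", surface_x3_um = 0)  # phase-stationary setup
  # 10 degrees already covers the whole Gaussian support here
  mags <- vapply(c(0.8, 1.5709, 10), function(th) {
    B <- acceptance_set(th, s$normal, k0)
    Mod(scattered_field_near(s, beam, k0, c(0, 0, 0), acceptance = B,
      n_nodes = 200))
  }, numeric(1))
  full <- Mod(scattered_field_near(s, beam, k0, c(0, 0, 0), n_nodes = 200))
  expect_true(all(diff(mags) > 0))
  expect_lte(mags[3], full * (1 + 1e-8))
  # a wide-open acceptance set recovers the unfiltered integral
  expect_equal(mags[3], full, tolerance = 1e-6)
})

test_that("near and far fields agree at long range", {
  k0 <- 4.8404
  beam <- beam_parameters(14.15, r0_um = 0)
  s <- layered_sample("mirror", surface_x3_um = 0)
  r <- 3e4
  En <- scattered_field_near(s, beam, k0, c(0, 0, r))
  Ef <- scattered_field_far(s, beam, k0, r, c(0, 0, 1))
  expect_equal(Mod(En), Mod(Ef), tolerance = 1e-2)
})

test_that("the result only depends on the surface plane, not the stored point", {
  k0 <- 4.8404
  beam <- beam_parameters(14.15, r0_um = -120)
  s <- layered_sample("mirror", tilt_deg = 2.75, surface_x3_um = -150)
  E1 <- scattered_field_near(s, beam, k0, c(0, 0, 0), n_nodes = 160)
  # slide the surface point along the in-plane tangent direction
  tangent <- c(s$normal[3], 0, -s$normal[1])
  s2 <- s
  s2$surface_point <- s$surface_point + 35 * tangent
  E2 <- scattered_field_near(s2, beam, k0, c(0, 0, 0), n_nodes = 160)
  expect_equal(E1, E2, tolerance = 1e-8)
})
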
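# Tensor-product Gauss-Legendre quadrature over a rectangle.
#
# The angular-spectrum integrands are smooth (a Gaussian spectral envelope
# times complex exponentials), so fixed-order Gauss-Legendre converges
# spectrally once the node count resolves the fastest oscillation. Node
# counts are either supplied or chosen from a coarse sample of the actual
# phase excursion of the integrand (Nyquist-type bound).

.gl_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n, a, b) {
  if (n < 2L) n <- 2L
  key <- as.character(n)
  ref <- .gl_cache[[key]]
  if (is.null(ref)) {
    ref <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- ref
  }
  list(x = (a + b) / 2 + (b - a) / 2 * ref$x, w = (b - a) / 2 * ref$w)
}

# f(k1, k2): vectorized over equal-length vectors, returning a complex vector
# (dim = 1) or a dim x N complex matrix. Chunked over the second axis to keep
# memory bounded for large node counts.
gl_quad2d <- function(f, xlim, ylim, nx, ny = nx, dim = 1L, chunk = 256L) {
  gx <- gl_nodes(nx, xlim[1], xlim[2])
  gy <- gl_nodes(ny, ylim[1], ylim[2])
  acc <- if (dim == 1L) 0 + 0i else rep(0 + 0i, dim)
  starts <- seq(1L, length(gy$x), by = chunk)
  for (s in starts) {
    jj <- s:min(s + chunk - 1L, length(gy$x))
    K1 <- rep(gx$x, times = length(jj))
    K2 <- rep(gy$x[jj], each = length(gx$x))
    W <- rep(gx$w, times = length(jj)) * rep(gy$w[jj], each = length(gx$x))
    v <- f(K1, K2)
    if (dim == 1L) {
      acc <- acc + sum(v * W)
    } else {
      acc <- acc + as.vector(v %*% W)
    }
  }
  acc
}

# Estimate per-axis node counts from the phase of `phase_fun(k1, k2)` (real,
# radians) sampled on a coarse grid: nodes ~ 3.2 per oscillation cycle along
# the worst row/column, floored and capped.
auto_gl_nodes <- function(phase_fun, xlim, ylim, floor_n = 48L, cap_n = 4096L,
                          probe = 17L) {
  px <- seq(xlim[1], xlim[2], length.out = probe)
  py <- seq(ylim[1], ylim[2], length.out = probe)
  P <- outer(px, py, phase_fun)
  rng_x <- max(apply(P, 2L, function(col) diff(range(col))))
  rng_y <- max(apply(P, 1L, function(row) diff(range(row))))
  n_of <- function(rng) {
    min(max(floor_n, ceiling(3.2 * rng / (2 * pi))), cap_n)
  }
  c(n_of(rng_x), n_of(rng_y))
}

# Closed form of the truncated Gaussian integral
#   int_lo^hi exp(-psi2 k^2) exp(-1i psi1 k) dk,   Re(psi2) > 0,
# by completing the square; complex error function via pracma::erfz, with a
# real fast path (pracma::erf) when everything is real.
gauss_segment_integral <- function(psi2, psi1, lo, hi) {
  if (Re(psi2) <= 0) stop("Re(psi2) must be positive", call. = FALSE)
  s <- sqrt(psi2)
  shift <- 1i * psi1 / (2 * psi2)
  pref <- exp(-psi1^2 / (4 * psi2)) * sqrt(pi / psi2) / 2
  zlo <- s * (lo + shift)
  zhi <- s * (hi + shift)
  if (Im(psi2) == 0 && all(Im(c(zlo, zhi)) == 0)) {
    pref * (pracma::erf(Re(zhi)) - pracma::erf(Re(zlo)))
  } else {
    pref * (pracma::erfz(zhi) - pracma::erfz(zlo))
  }
}
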
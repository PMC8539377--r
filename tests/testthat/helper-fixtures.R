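# Shared fixtures: the instrument-like configuration used across tests.
# Everything is built in code; heavier simulated objects are memoized per
# test run so several test files can share them.

table_beam <- function(r0 = 0) beam_parameters(14.15, r0_um = r0)

sweep_grid <- function(n = 700L) wavenumber_grid(4.7835, 4.8973, n)

tilted_normal <- function(tilt_deg) {
  c(sin(deg2rad_t(tilt_deg)), 0, cos(deg2rad_t(tilt_deg)))
}

deg2rad_t <- function(x) x * pi / 180

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# independent 1-D Gauss-Legendre sum (oracle path, does not reuse the
# package's 2-D integrator)
gl_sum_1d <- function(f, lo, hi, n) {
  g <- pracma::gaussLegendre(n, lo, hi)
  sum(f(g$x) * g$w)
}

si_t <- function(x) ifelse(x == 0, 1, sin(x) / x)
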
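---
title: "A Gaussian-beam forward model for swept-source OCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Gaussian-beam forward model for swept-source OCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsim)
```

## The model

A swept-source OCT system records, for every wavenumber $k_0$ of a laser
sweep, the interference between light back-scattered by the sample and a
reference beam. Plane-wave descriptions of this process cannot express the
two effects that dominate real data from a focused probe: the loss of signal
when the sample surface is tilted away from normal incidence, and the loss
of signal when the surface moves out of the focal plane. `octsim` implements
a model that keeps both, by treating the illumination as a focused Gaussian
beam decomposed into an angular spectrum of plane waves.

**Illumination.** The beam is a solution of the vector Helmholtz equation
built from plane-wave components indexed by the transverse wavevector
$(k_1,k_2)$, with a Gaussian spectral weight
$\check f(k_1,k_2) = A\,e^{-a(k_1^2+k_2^2)}$, $a = w_0^2/4$, supported
inside the propagating disk $k_1^2+k_2^2<k_0^2$. Here $w_0$ is the beam
waist radius at the focus; the focal plane sits at $x_3 = r_0$ and the beam
propagates toward negative $x_3$. Each component carries a polarization
lift that makes the field divergence-free (`polarization_lift()`); the
detection chain itself is scalar (see *Design choices*).

**Sample.** Locally the sample is a stack of parallel planar boundaries
with unit normal $\nu = (\sin\theta_\Omega, 0, \cos\theta_\Omega)$ and
constant refractive indices. Each plane-wave component reflects specularly,
$k \mapsto k_r = k - 2\langle k,\nu\rangle\nu$, weighted by a reflection
coefficient $\beta_S(k_1,k_2)$: 1 for an ideal mirror, a Fresnel
coefficient for a single dielectric boundary, and for a parallel slab of
thickness $d$ and index $n_1$ the first-order two-boundary coefficient
$\beta_0 - \beta_0(1-\beta_0^2)e^{-i k_0 2 n_1 d\cos\theta_t}$ (higher-order
internal reflections are neglected). The transmission angle $\theta_t$
follows Snell's law and may be complex beyond the critical angle.

**Scan lens.** Only reflected components whose direction lies within the
angle of acceptance $\theta_{\max}$ of the detection axis are collected.
This acceptance set in the $(k_1,k_2)$ plane is nearly a disk of radius
$k_0\sin\theta_{\max}$ displaced by $-k_0\sin 2\theta_\Omega$ along $k_1$;
the package integrates over either the exact set or its circumscribing
rectangle (half-widths $L_1, L_2$), which is the form used for calibration.

**Detection.** The filtered sample field and the reference field are
combined on a dual-balance detector, which isolates the cross-correlation
term $M(k_0) = -\mathrm{Re}\,\langle E_S, \overline{E_R}\rangle$. Sweeping
$k_0$ over the band $[k_{\min}, k_{\max}]$ yields an A-scan whose dominant
oscillation frequency is the optical path offset $\Theta_0$ between the
sample surface and the zero-delay plane — approximately twice the
geometric depth offset for small tilt.

## Inverse procedures

**Beam calibration.** With a mirror mounted on a goniometer whose pivot
coincides with the focus, the detected power as a function of tilt reduces
to a product of two truncated Gaussian line integrals over the acceptance
rectangle,
$$G(\theta_\Omega; w_0, \theta_{\max}) = |\tau|^2\,
\Bigl|\tfrac{1}{4\pi^2} I_1 I_2\Bigr|^2, \qquad
I_1 = \int_{-L_1-c}^{\,L_1-c} e^{-\psi_2 k^2 - i\psi_1 k}\,dk,\quad
I_2 = \int_{-L_2}^{\,L_2} e^{-\psi_2 k^2}\,dk,$$
with $c = k_0\sin 2\theta_\Omega$ and the phase elements
$\psi_1 = 2\nu_1\nu_3 x_{\Omega,3}$,
$\psi_2 = a + \tfrac{i}{k_0}(\nu_3^2 x_{\Omega,3} - r_0/2)$. The two
integrals have closed forms through the (complex) error function;
`power_angle_model()` evaluates them and cross-checks against direct
Gauss–Legendre quadrature in the tests. `fit_beam_parameters()` extracts
$(w_0, \theta_{\max})$ by least squares, profiling the unknown scale
$|\tau|^2$ analytically (it enters linearly). Because such objectives can
be multimodal when the surface is displaced from the pivot, the optimizer
is a deterministic two-stage search: a $32\times 32$ log-spaced grid over
$w_0 \in [4, 50]$ µm, $\theta_{\max} \in [0.2, 6]°$, followed by
Nelder–Mead refinement in log-parameters.

**Depth, tilt and thickness.** An A-scan is analysed through its
band-limited Fourier intensity
$I(\kappa) = \tfrac{1}{2\pi}\bigl|\int_{k_{\min}}^{k_{\max}} M(k_0)
e^{-i k_0\kappa}dk_0\bigr|^2$, computed with trapezoid weights and
zero-padded FFT evaluation. For the reduced single-surface model
$M(k_0) = K k_0^2 e^{-k_0^2\sigma^2}\cos(k_0\Theta_0)$, with
$\sigma = (w_0/2)\sin 2\theta_\Omega$, the transform is a pair of sinc
kernels centred at $\pm\Theta_0$ (`reduced_model_transform()`), so the peak
of $I$ on the positive half-line recovers $\Theta_0$. `estimate_tilt()`
converts per-A-scan peaks to depths (factor 2, small-tilt assumption) and
fits a line against the lateral positions; `estimate_thickness()` inverts
the slab round-trip phase, $d = \Delta\Theta_0 / (2 n_1\cos\theta_t)$.
Through-focus series are summarized by the mean over A-scans of the
maximum depth intensity per B-scan (`bscan_focus_statistic()`), normalized
to the series maximum.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `w0_um` | beam waist radius at focus | 14.15 µm | calibrated value of the modelled instrument |
| `theta_max_deg` | scan-lens angle of acceptance | 1.5709° | calibrated value |
| `kmin`, `kmax` | sweep band | 4.7835, 4.8973 µm⁻¹ | a 1300 nm source with 30 nm bandwidth |
| `n` (grid) | sweep samples | 700 | acquisition length of the digitizer |
| `rD_um` | scan-lens distance | 60 000 µm | sets the reference amplitude scale |
| `tilt_deg` | sample tilt | 2.75° | typical deliberate tilt used to avoid specular saturation |
| `n1`, `thickness_um` | coverglass index / thickness | 1.5088, 150 µm | index of the glass at 1300 nm; 150 µm is a standard #1 coverglass |
| `pad_factor` | FFT zero-padding | 8 | axial pixel ≈ 6.9 µm, matching zero-padded acquisition practice |
| DC exclusion | guard band in `locate_peak()` | 5 κ-pixels | peaks must sit away from the origin to be separable from the DC lobe |

## The synthetic-data generator

`generate_power_angle()` emulates the goniometer sweep: 25 angles from −1°
to 1° in 5-arc-minute steps, 6 repeats, multiplicative Gaussian noise
(default 1%) on each power reading — the noise a power meter actually
reports. `generate_focus_series()` emulates the motorized-stage
experiments: 11 stage positions for a mirror and 7 for a coverglass,
centred on the focus-coincidence position, 9.8 µm lateral pixel, additive
Gaussian noise (default 2% of the series peak) on the detected spectrum.
All randomness flows through one seed per recipe; identical recipes
produce identical datasets, and every ground-truth quantity needed to
score a recovery (depths, tilt, thickness, focus position, zero delay) is
returned alongside the data.

What the generator does **not** emulate: speckle from rough or diffusely
scattering surfaces, detector nonlinearity and digitizer offset (data are
already centred, as after background subtraction), dispersion, wavelength-
dependent source power, and scan-lens field curvature. Passing recovery
tests on these data therefore demonstrates the internal consistency of the
model and estimators — not robustness to every artefact of real
instruments.

## Numerical choices

* **Quadrature.** All angular-spectrum integrals use tensor-product
  Gauss–Legendre rules. The unfiltered integrals run over the square
  enclosing the disk where the Gaussian weight exceeds $10^{-8}$ of its
  peak ($\rho_0 = \sqrt{\ln 10^8 / a}$), which bounds the truncation error
  analytically; acceptance-filtered integrals run exactly over the
  rectangle. Node counts follow a sampled phase-excursion estimate
  (≈3.2 nodes per oscillation cycle) or an explicit `n_nodes`; A-scan
  simulation uses 32 nodes per axis, which node-doubling shows to be
  converged to ~$10^{-13}$ for the narrow acceptance rectangle. Evanescent
  components are never integrated.
* **Detector reference point.** The detected fields are compared at a
  reference point at the origin rather than literally at the scan lens
  6 cm away. An ideal collimating lens cancels the propagation phase
  common to all accepted components; carrying that quadratic phase
  ($\sim r_D \rho^2/2k_0$, orders of magnitude larger than the Gaussian
  width $a$) through the acceptance integral would suppress the
  through-focus contrast the model exists to describe. The reference-arm
  phase is referenced at the same point, so only path differences reach
  the detected cross term. `reference_field()` still reproduces the
  textbook far-field expression at $x_D = r_D e_3$ when called without an
  evaluation point.
* **Focus coincidence** is defined by the vanishing of the focus distance
  $d = \nu_3^2 x_{\Omega,3} - r_0/2$ — the condition under which the
  reflected beam refocuses at the detection point. Generator stage grids
  are centred there.
* **Fourier convention.** $I(\kappa)$ uses the symmetric
  $1/\sqrt{2\pi}$-per-transform normalization (squared), which is the
  convention under which the two-sinc surrogate and the direct transform
  agree quantitatively; peak locations are independent of this choice.
* **Fresnel sign convention.** Normal-incidence reflection from a denser
  medium has negative perpendicular amplitude; the perfect mirror is a
  reflector flag with $|\beta| = 1$ (not a large finite index, which would
  only add overflow risk). Detection uses magnitudes and relative phases,
  so the convention is observable only through internal consistency.
* **Degenerate inputs.** Grazing far-field directions ($c_3 = 0$) are
  rejected rather than assigned a sign; identically zero spectra and flat
  calibration data raise errors naming the defect; peaks are refined by a
  three-point parabola only when the curvature is negative.
* **Scalar detection.** TE/TM Fresnel coefficients and the polarization
  lift are implemented and tested, but the detection chain contracts the
  fields to scalars — for the specular samples modelled here the
  polarized and scalar pipelines differ only in an overall scale, which
  normalization removes.

## Problem sizes

The shipped defaults are desk-scale: 700-point sweeps, 32²-node acceptance
quadrature per wavenumber (~0.5 s per A-scan), 8 (mirror) or 64
(coverglass) A-scans per B-scan. The coverglass B-scan is wider because the
tilt estimate is a regression of per-A-scan peak positions whose residual
jitter — dominated by sidelobe cross-talk between the front- and
back-surface sinc kernels — averages down with the lateral span. The
unfiltered near-field/far-field comparisons use automatically scaled node
counts up to a few thousand per axis at $r = 10^5$ µm.

## Known limitations

* At most two boundaries; first-order internal reflections only.
* The factor-2 depth conversion and the tilt estimator assume small tilt;
  at 2.75° the induced bias is below 0.01°.
* The exact acceptance set is supported for membership queries and masked
  quadrature, but masked Gauss–Legendre converges slowly at the set's
  boundary; the rectangle path is the quantitative one.
* The power-angle model fixes the surface at the goniometer pivot in the
  focal plane ($r_0 = x_{\Omega,3} = 0$ by default); displaced
  configurations are supported but make the objective oscillatory, which
  is why the fitter keeps a global grid stage.
* Absorbing media, curved boundaries and diffuse scattering are out of
  scope.
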
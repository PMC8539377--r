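Package: octsim
Title: Gaussian-Beam Forward Model and Calibration for Swept-Source
    Optical Coherence Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative forward model of signal formation in a swept-source
    optical coherence tomography (OCT) system: Gaussian-beam illumination as
    an angular spectrum of plane waves, Fresnel reflection from tilted layered
    samples, scan-lens acceptance filtering, and dual-balance detection.
    Includes the two calibration and inversion procedures built on the model:
    least-squares extraction of the beam waist and the angle of acceptance
    from power-versus-angle measurements of a mirror, and recovery of surface
    depth, tilt angle and slab thickness from the band-limited Fourier
    transform of A-scan spectra. A seeded synthetic-data generator emulates
    the power-versus-angle sweep and through-focus B-scan series of a mirror
    and a coverglass.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
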
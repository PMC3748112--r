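---
title: "ROI-focused dual-panel TOF-PET: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI-focused dual-panel TOF-PET: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(panelpet)
```

## The imaging problem

A conventional PET ring surrounds the whole torso even when the clinical
question concerns a small region. `panelpet` studies the alternative: two
opposing flat panel detectors (28 cm long, 2 mm crystal pitch, 30 cm apart by
default) positioned over a region of interest, operating in 2D transverse
mode. Such a scanner has severely limited angular coverage — only lines of
response (LORs) crossing from one panel to the other exist — so classical
tomographic reconstruction is ill-posed: structures elongate along the
direction perpendicular to the panels and X-shaped streaks appear. Per-event
time-of-flight (TOF) information restores localization along each LOR and is
what makes the design viable.

Coordinates: the origin is the FOV centre, x runs parallel to the panels,
y perpendicular; the top panel face is at y = +150 mm. All lengths are mm,
times ps, and c = 0.299792458 mm/ps. A measured arrival-time difference
`dt = t_top - t_bottom` places the annihilation at the LOR midpoint displaced
by `c*dt/2` toward the bottom crystal.

## The windowed list-mode OSEM algorithm

The reconstruction is maximum-likelihood list-mode EM with a factorized
system model

    p(j; i, t) = p_geom(j; i) * h_TOF(u_j - c t / 2),

where `p_geom(j; i)` is the probability that an emission in pixel j is
detected by crystal pair i, and `h_TOF` is a Gaussian along the LOR axis
whose FWHM is the system timing resolution mapped to space
(`sigma_x = c * sigma_t / 2`; 300 ps FWHM gives `sigma_x` of about 19.1 mm).
The EM update for a chronological subset B of events is

    lambda_j <- (lambda_j / s_j) * sum_{k in B} p(j; i_k, t_k) /
                sum_{j'} p(j'; i_k, t_k) lambda_{j'}

with `s_j` the sensitivity: the total detection probability of pixel j over
all crystal pairs and all measurable time differences. Events are divided
chronologically into 16 subsets by default; all in-FOV pixels start at a
uniform positive value; zero-sensitivity pixels stay exactly zero. The
stopping rule is a fixed iteration count (default 10) because the interesting
behaviour — contrast recovery versus iteration — is itself an output
(`crc_vs_iteration()`); contrast typically stabilizes after 2–3 iterations at
good timing resolution.

For ROI imaging the data stream itself is windowed: an event is kept only if
its TOF-implied position (computed from the *measured*, blurred time
difference — the only quantity a scanner has) falls inside an axis-aligned
ROI rectangle. The sensitivity must then be truncated consistently: only time
bins whose centre maps into the ROI contribute to `s_j`. Discrimination and
truncation use the same filter, so no correction terms are needed; the price
is that some in-ROI annihilations are lost and some out-of-ROI ones kept,
which the matched sensitivity accounts for in expectation.

### The conventional mode is the windowed mode at ROI = FOV

A subtle design decision: events whose blurred TOF position falls outside the
inter-panel rectangle carry no consistent source location, and this package's
conventional mode discards them — it *is* the windowed algorithm with the ROI
set to the whole FOV. Consequently `sensitivity_full()` is the FOV-truncated
sum. For every pixel more than a few `sigma_x` from a panel face the TOF bin
masses sum to one and `s_j` equals the plain geometric sum
(`geometric_sensitivity()`); the two definitions differ only within a
blur-width of the panel faces. The payoff is an exact algebraic identity —
the windowed reconstruction with ROI = FOV is *bit-identical* to the
conventional one — which the test suite asserts, and which makes the ROI
algorithm a strict generalization rather than a sibling code path.

### Geometric system model

The factor `p_geom(j; i)` is computed analytically rather than from a
detector-physics Monte Carlo. For two crystal faces of width w at separation
D, the uniform (position, angle) emission measure induces a measure on the
lines joining the faces with Jacobian `D^2 / l^3` (l the line length), so

    p_geom(j; i) = (1 / (pi * A_pix)) *
                   int_{face_a} int_{face_b} chord_j(x_a, x_b) * D^2 / l^3
                   dx_a dx_b.

This is evaluated with a composite Gauss–Legendre rule over the two faces
(default about 12 nodes per face), tracing each node line through the pixel
grid with Siddon traversal. An *even* number of quadrature subintervals is
used so that no node line can run exactly along a pixel boundary when the
grid aligns with the crystal lattice (the single centre line of a directly
opposing pair does exactly that, and a one-line "axis ray" model would put
its entire weight on one side — measurably wrong against a Monte Carlo
estimate). The package carries its own brute-force oracle,
`mc_system_matrix_oracle()`, against which the analytic weights agree to a
few percent at the default quadrature order and under 2% at 24 nodes per
face; the remaining deviation in such comparisons is dominated by the
oracle's binomial noise.

EM is invariant to a global scale of `p`, so the absolute normalization
matters only for interpretability; the chosen one makes
`sum_i p_geom(j; i)` the per-decay detection probability (about
`(2/pi) atan(140/150) = 0.477` at the FOV centre of the default geometry).

### Numerical choices

* TOF factors per event use the continuous Gaussian density at the measured
  `dt`; time bins (default 25 ps, far below the 100 ps best studied FWHM)
  appear only in sensitivity summation. A degenerate FWHM = 0 kernel falls
  back to an indicator over the pixel's projected extent.
* Gaussian event factors are evaluated within 10 sigma of the TOF position
  (contributions beyond are below 1e-21 of the mode); the dense-matrix
  comparison oracle uses no truncation and agrees to 1e-10 per pixel.
* Events with a zero forward projection (possible at ROI corners) are
  skipped and counted, not fatal.
* Subset order is sequential chronological — no randomization — so every
  reconstruction is bit-reproducible from the data and configuration.
* Bin membership at the half-open ROI edges is decided by the bin-centre
  rule, applied literally at the boundary bins.

## The simulator and what it does (not) emulate

`simulate_listmode()` samples decay positions proportional to the activity
image (uniform within a pixel), draws an emission angle uniform on `[0, pi)`,
and propagates two exactly anti-parallel photons to the panel faces; struck
crystals are found by front-face position (no depth of interaction). True
time differences come from the path-length difference; measurement blur adds
Gaussian timing noise (`sigma_t = FWHM / 2.355`) and Gaussian energy noise
(0.13 fractional resolution at 511 keV by default). A 400–600 keV energy
window and a 6 ns coincidence window are applied. The sweep experiments use
the resampling shortcut: one acquisition with perfect resolution, re-blurred
to each target timing resolution (`reblur_listmode()`); a two-sample
Kolmogorov–Smirnov test in the suite confirms distributional equivalence with
direct simulation.

Deliberately not modelled, matching the study conditions this package
reproduces: positron range, photon acollinearity, attenuation, scattered and
random coincidences, dead time and count-rate effects. Every simulated
coincidence is a true one. Passing tests therefore demonstrate the geometry,
TOF and algorithmic behaviour of the design — not its performance under a
realistic event mix, where scatter and randoms from outside the ROI would
additionally contaminate (and the windowed discrimination would partly
reject) the data.

Activity values act only as relative sampling weights; the count scale is set
by `n_decays` (the study reports count totals rather than durations, so
acquisition-time bookkeeping is out of scope).

## Phantoms

`nema_iq_phantom()` is a 2D reduction of the NEMA NU 2-2001 image-quality
phantom: four hot discs (10, 13, 17, 22 mm diameter; default 4:1 uptake
against a 5.3 kBq/cc background) and two cold discs (28, 37 mm), equally
spaced on a ring inside an elliptical warm body. The body axes
(260 x 200 mm), lesion ring radius (57 mm) and the 160 x 160 mm default ROI
are package defaults chosen so that all six lesions fit inside an ROI
strictly inside the 280 x 300 mm FOV; all are configurable.
`abdomen_phantom()` is a fully parametric abdominal section (elliptical body,
crescent liver, spine, one low-uptake lesion at 1.5 times the muscle level
inside the liver) standing in for a voxelized anatomical phantom without any
external data dependency — the regional intensities are arbitrary relative
levels by construction.

Rasterization is pixel-centre-in-region with no anti-aliasing, so region
masks are exact pixel sets and the contrast recovery coefficients have
unambiguous definitions. The smallest (10 mm) disc carries about 1–2%
discretization error in area at 1 mm pixels.

## Evaluation

Hot and cold contrast recovery coefficients are

    CRC_hot  = (m_lesion / m_bg - 1) / (R - 1),      R = true uptake ratio,
    CRC_cold = 1 - m_lesion / m_bg,

with the background mean taken over a central 60 mm disc minus any lesion
overlap. Both are scale-invariant and equal 1 exactly on the true phantom.

The limited-angle stretch is quantified by `elongation_ratio()`: the ratio of
vertical to horizontal FWHM of a lesion, measured on band-averaged profiles
(default 5 mm half-band) through the lesion's intensity centroid after light
Gaussian smoothing (default 3 mm FWHM). Both choices exist because list-mode
OSEM images at realistic counts are speckled: a single interpolated line
through a noisy image measures the width of a noise grain, not of the lesion.
A profile that never falls below half maximum inside the analysis window is
censored at the window edge and flagged, making the ratio a lower bound —
adequate for ordering timing resolutions, which is how the package uses it.
The window must be kept clear of the bright rectangle artifact that windowed
reconstructions develop along the ROI boundary.

`tr_sweep()` packages the timing-resolution experiment: one perfect-timing
acquisition, re-blur to each FWHM in the sweep (100 ps to 1 ns is the studied
range), windowed reconstruction at fixed counts and iterations, then CRC,
elongation and kept-event counts per resolution.

## Worked example

A scaled-down end-to-end run (about a minute; the package's tests exercise
the full-scale conditions):

```{r example, eval = FALSE}
geom <- panel_geometry()                  # 280 mm panels, 300 mm apart
phantom <- nema_iq_phantom(geom)
roi <- roi_window(-80, 80, -80, 80)

lm <- simulate_listmode(phantom$image, geom,
                        acquisition_config(2e5, timing_fwhm = 300, seed = 1))
cache <- build_system_cache(geom, phantom$image)
rec <- reconstruct_windowed(lm, roi, geom = geom, cache = cache,
                            n_iterations = 10)
rec
crc_table(rec$image, phantom, iteration = 10, timing_fwhm = 300)
plot(rec)
```

## Problem sizes used by the test suite

The suite verifies the algorithmic identities on small instances (8–32
crystal panels, 12 x 12 to 32 x 40 pixel grids) where a dense system matrix
and a brute-force Monte Carlo oracle are affordable, and the imaging claims
at full scale: the 280 x 300 mm grid at 1 mm pixels, 10^6 decays at 300 ps
for lesion detectability, 6.5 x 10^5 decays per arm across five seeds for the
timing-resolution ordering, and 10^7 decays per pixel for the system-matrix
oracle comparison. These sizes were chosen as the smallest at which the
statistical checks have comfortable power.

## Known limitations

* 2D transverse imaging only; no axial extent, no ring or tilted-panel
  geometries.
* The analytic system model covers geometry only — no crystal penetration,
  inter-crystal scatter or block effects; detector quantum efficiency is a
  single configurable scalar.
* No attenuation, scatter, randoms or normalization corrections; the
  simulator generates none of these effects either, so quantitative accuracy
  on real data is out of scope.
* Rectangular, axis-aligned ROIs only (`point_in_roi()` is the single
  extension point for other shapes).
* The ROI must lie inside the FOV; the windowed and conventional modes
  coincide exactly when the ROI equals the FOV rectangle.
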
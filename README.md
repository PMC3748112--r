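# panelpet

Simulation and reconstruction toolkit for an ROI-focused PET scanner built
from two opposing flat panel detectors.

## The problem

PET scanners are usually full rings sized for a torso, yet many imaging
questions concern one small region. A compact scanner made of two panel
detectors placed over the region of interest (ROI) would be cheaper and
portable — but two opposing panels see only a narrow range of projection
angles, and limited-angle tomography produces elongation and streak
artifacts. Time-of-flight (TOF) measurement rescues the design: the arrival
time difference `dt` of the two 511 keV photons localizes each annihilation
along its line of response at `d = c*dt/2` from the midpoint.

`panelpet` implements the complete study pipeline for this concept, for
researchers in emission tomography and detector design:

* **Geometry** — two parallel panels (defaults: 28 cm long, 2 mm crystal
  pitch, 30 cm face-to-face), 2D transverse imaging.
* **Phantoms** — a 2D NEMA-IQ-style phantom (four hot lesions of 10/13/17/22
  mm at 4:1 uptake, two cold lesions of 28/37 mm, 5.3 kBq/cc background) and
  a parametric abdomen with liver, spine and a 1.5:1 low-uptake lesion.
* **Monte Carlo list-mode simulator** — back-to-back photon transport,
  Gaussian timing/energy blur, 400–600 keV and 6 ns acquisition windows.
* **Windowed list-mode OSEM** — the core algorithm. Conventional TOF list-mode
  EM over chronological ordered subsets:

  ```
  lambda_j <- (lambda_j / s_j) * sum_k  p(j; i_k, t_k) / sum_j' p(j'; i_k, t_k) lambda_j'
  p(j; i, t) = p_geom(j; i) * Gauss(u_j - c t / 2; sigma_x),   sigma_x = c * sigma_t / 2
  ```

  and its ROI-windowed form: events are kept only if their TOF position
  falls inside the ROI, and the sensitivity `s_j` is truncated to the time
  bins whose positions lie inside the ROI. The conventional mode is exactly
  the windowed mode with ROI = full FOV.
* **Evaluation** — intensity profiles, hot/cold contrast recovery
  coefficients (CRC), CRC-vs-iteration curves, lesion elongation ratios, and
  a timing-resolution sweep (100 ps – 1 ns FWHM).

## Worked example

NEMA-IQ phantom, 10^6 decays at 300 ps timing resolution, windowed OSEM with
16 subsets and 10 iterations (a few minutes on one core):

```r
library(panelpet)

geom    <- panel_geometry()                    # 280 mm panels, 300 mm apart
phantom <- nema_iq_phantom(geom)               # 5.3 kBq/cc, 4:1 hot lesions
roi     <- roi_window(-80, 80, -80, 80)

lm    <- simulate_listmode(phantom$image, geom,
                           acquisition_config(1e6, timing_fwhm = 300, seed = 11))
cache <- build_system_cache(geom, phantom$image)
rec   <- reconstruct_windowed(lm, roi, geom = geom, cache = cache,
                              n_iterations = 10)
rec$counts$total   # 306099 coincidences acquired
rec$counts$used    # 218903 kept by the TOF window (71.5%)

crc_table(rec$image, phantom, iteration = 10, timing_fwhm = 300)
#>      lesion kind diameter       crc
#> 1  hot_10mm  hot       10 0.4868197
#> 2  hot_13mm  hot       13 0.7280906
#> 3  hot_17mm  hot       17 0.7846249
#> 4  hot_22mm  hot       22 0.7658269
#> 5 cold_28mm cold       28 0.6712723
#> 6 cold_37mm cold       37 0.7264151

plot(rec)          # cropped ROI image; plot(rec, crop = FALSE) shows the
                   # rectangle artifact along the ROI edge
```

Every lesion — including the smallest, 10 mm — is recovered above background
(contrast recovery rises with lesion size), each lesion centroid lands within
1 mm of its true position, and the TOF window discards ~29% of the events
before reconstruction even starts. Vertical elongation of lesions, the
hallmark limited-angle artifact, shrinks as the timing resolution improves;
`tr_sweep()` runs that experiment end to end.

## Scope

2D transverse imaging of true coincidences only: positron range,
acollinearity, attenuation, scatter, randoms and count-rate effects are
deliberately outside the model (and the simulator). See the methods vignette
(`vignettes/roi-panel-pet.Rmd`) for the model derivations, numerical choices
and limitations.
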
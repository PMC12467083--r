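---
title: "Stiffness mapping with a four-FBG palpation probe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stiffness mapping with a four-FBG palpation probe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palpmap)
```

## The measurement model

A palpation probe for endoscopic surgery carries four fiber Bragg gratings
(FBGs) embedded in an elastic hemispherical silicone dome, placed
symmetrically at 90° around the dome base. Each grating reflects a narrow
band centered at its Bragg wavelength; mechanical strain of the dome shifts
that wavelength. One interrogation frame is the reflection spectrum of all
four gratings on a uniform wavelength grid — by default 1510–1590 nm at the
2 pm hardware resolution, with nominal Bragg peaks at 1520/1540/1560/1580 nm.
A real probe's gratings sit at whatever wavelengths its inscription chose —
four well-separated C-band peaks — so these defaults are configurable
stand-ins; everything downstream depends only on *shifts*, not absolute
positions.

The forward model in `synth_spectrum()` is a sum of Gaussian peaks (default
FWHM 60 pm) scaled by channel reflectivity (~30%) and by a source envelope,
on a constant detector floor, plus additive white Gaussian intensity noise
clipped at zero. Two deliberate simplifications:

* **Gaussian peaks, not coupled-mode physics.** The inverse model fits
  Gaussians, so the forward model uses the same family; side lobes,
  polarization and chirp are out of scope.
* **A linear gain ramp as the default envelope.** The interrogator emits
  more optical power towards the red end of the sweep, which makes
  equal-reflectivity gratings show unequal peak amplitudes. A linear ramp
  (0.4 → 1.0 across the grid) reproduces this qualitatively; a flat envelope
  (`flat_envelope()`) is available. No pipeline stage consumes amplitude, so
  the envelope only exercises robustness of the fits.
* **Noise.** The interrogator's noise floor is not characterized in print;
  `sigma_rel = 0.01` (1% of the tallest peak) is the package's documented
  assumption, chosen as clearly visible noise that still leaves the peaks
  clean, and it is the level at which the localization study below is run.

## Sub-resolution peak localization

Each spectrum is partitioned into four windows (`partition_windows()`), with
interior boundaries at the midpoints between adjacent nominal centers — any
fixed division of the sweep would do, and the midpoint rule gives each peak
symmetric headroom for motion in either direction. In each window,
`fit_gaussian_peak()` fits

$$I(\lambda) = A \exp\!\left(-\frac{(\lambda-\mu)^2}{2\sigma^2}\right) + b$$

by bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`, analytic
Jacobian, `ftol = ptol = 1e-10`, 200 iterations). The constant baseline $b$
is included because measured spectra sit on a non-zero floor; only the
center $\mu$ feeds the stiffness statistic. Numerical choices:

* **Initialization** from the raw samples: center at the window argmax
  (smallest-wavelength maximum on ties), amplitude at max−min, baseline at
  the minimum, width from the configured FWHM.
* **Bounds**: $\mu$ inside the window, $\sigma$ in 0.2–5× the initial
  width, $A \ge 0$. A converged fit whose center sits at a window bound is
  reported `converged = FALSE` ("pinned"), as are flat windows — failures
  are always flagged, never returned as silently wrong numbers.
* **Support restriction**: samples further than 25×FWHM from the initial
  center only pin the constant baseline, so they are dropped (keeping at
  least 50 samples) to make fits on wide windows cheap. This moves the
  center estimate by far less than the localization floor.
* **Working coordinates**: the window is recentered and scaled to pm before
  fitting so the Jacobian columns are comparably scaled.

On noiseless data the fitted center agrees with an independent brute-force
oracle — parabolic interpolation of the log-intensity on a 100× oversampled
rendering of the same Gaussian — to better than 0.01 pm (the log of a
Gaussian is exactly parabolic, so the oracle is exact up to its own grid).

`localization_precision()` measures the estimator's precision as used by the
acceptance study: single peaks with uniformly off-grid true centers, 2 pm
sampling, 1% noise, 1000 trials. A closed-form benchmark for this setting is
the Cramér–Rao bound for the center of a sampled Gaussian in white noise,

$$\sigma_\mu \;=\; \frac{\sigma_n}{A}\sqrt{\frac{2\,\Delta\,s}{\sqrt{\pi}}}
 \;\approx\; 0.076\ \mathrm{pm}$$

for grid step $\Delta = 2$ pm, peak width $s = 25.5$ pm (60 pm FWHM) and
$\sigma_n/A = 0.01$, giving a 95th-percentile absolute error of about
$1.96\,\sigma_\mu \approx 0.149$ pm. The fitted estimator attains this bound
(measured ≈ 0.15 pm), i.e. it is statistically efficient: at this noise
level no estimator can do better, and sub-0.1 pm figures require either
lower noise (≈0.65% or less), narrower peaks, or frame averaging.

```{r mc, eval = FALSE}
localization_precision(n_trials = 1000, seed = 1)$p95_pm
```

## From shifts to relative stiffness

For one press point, `compute_shifts()` takes the per-channel difference of
fitted centers between the pressed and contact acquisitions (pm, signed:
red-shift positive). The computation is refused for the whole point if any
channel failed — the statistic needs all four. The per-point statistic is

$$S = \sum_{i=1}^{4} |\Delta\lambda_{B,i}| \quad[\mathrm{pm}]$$

and `normalize_session()` maps it to $s_{\mathrm{norm}} =
(S-S_{\min})/(S_{\max}-S_{\min})$, exactly 1 at the stiffest point and
exactly 0 at the softest. Design choices:

* **Normalization scope is one session.** Scores are comparable only within
  one scan; the package exposes no cross-session normalization because the
  method claims none.
* **Degenerate sessions** (all $S$ equal within 1e-9 relative — far below
  any physical contrast, above numerical fit residuals) map to all-zeros
  with a warning: "no contrast" is safer reported as uniformly softest than
  as `NaN`.
* **Only wavelength shifts are used.** Peak-amplitude changes under large
  deformation are a known, more sensitive channel, but require calibration
  the method does not define; amplitudes are recorded in the fit reports and
  otherwise unused.

`fit_calibration()` fits the probe-head bench characterizations (mean shift
vs. indentation depth; mean shift vs. Shore A hardness at fixed 2 mm
indentation) as ordinary least-squares lines with $r^2$ and the measured
support; the response is linear in the working range and no heteroscedastic
weighting is justified by the available data. Predictions outside the
support are flagged as extrapolations.

## Heat-map reconstruction

`interpolate_map()` reconstructs the stiffness field from the scattered
press points by piecewise-linear barycentric interpolation on the Delaunay
triangulation (`interp::interp`), with nearest-neighbour values outside the
convex hull. The linear interpolant was chosen over splines deliberately: it
is exact at the data points and can never overshoot the input extremes, so
the [0, 1] normalization survives mapping. The output grid defaults to
50 × 50 nodes over the region of interest; coordinates are continuous, in
mm, origin at the lower-left of the scanned area. Collinear-only point sets
are refused for 2D contouring with an explicit message; one or two points
fall back to nearest-neighbour maps; duplicate coordinates with conflicting
values are refused naming the offending points.

`detect_stiff_region()` thresholds at a fraction of the map maximum
(default 0.5) and labels 4-connected components of hot cells (via `igraph`),
reporting centroid, bounding box and area fraction — a quantitative handle
on the qualitative "red region" a surgeon reads off the heat map.

## The phantom simulator

`phantom_field()` abstracts the bench validation — a metallic blade slid
under a marked 4 cm × 4 cm area of liver — as a uniform background
stiffness with a stiff line segment: stiffness
`background × multiplier × depth_attenuation` within the segment's
half-width, cosine-tapered back to background over one half-width beyond
the edge. Defaults: 40 mm × 40 mm region, background 1, multiplier 30 for a
metal object, depth attenuation 1, half-width 2 mm.

`simulate_press()` produces a contact spectrum at the nominal centers and a
pressed spectrum with per-channel shifts

```
shift_i = response_slope × press_depth × sensed_stiffness × w_i
```

* **Linear response** in press depth, per the probe's bench-measured
  linearity in its working range. `response_slope = 5` pm/mm/unit-stiffness
  makes a 2 mm press on background tissue shift each channel ~10 pm — well
  above the localization floor, well below the >1 nm large-deformation
  regime where amplitude losses appear (not simulated).
* **Contact geometry.** Directly over the inclusion the press senses the
  local field. Laterally offset beyond the taper but within an influence
  radius (default 8 mm), it senses the hard object through the flank of the
  dome at `side_contact_attenuation` (default 0.1) of the direct peak
  response, never below background: direct contact reads about an order of
  magnitude stronger than side contact, and the attenuated-peak form (rather
  than background-plus-attenuated-excess) is what makes that ratio hold
  exactly at the default attenuation. Beyond the influence radius only
  background is sensed.
* **Sign pattern** $w_i$: a centered press flattens the dome and loads all
  four gratings alike (all red-shift); a side contact bends the dome towards
  the object, splitting the grating pair along the offset axis into tension
  on the near side and compression (blue-shift) on the far side. All
  $|w_i| = 1$, so the summed statistic depends on geometry only through the
  sensed stiffness.

`simulate_session()` runs one press per protocol point, optionally writing
two-column spectrum files plus a JSON manifest — the exact inputs
`run_pipeline()` consumes — fully reproducible from the protocol seed
(per-point sub-seeds are derived deterministically from it).

### What the simulator does and does not emulate

It reproduces the statistical structure the pipeline assumes: four Gaussian
peaks with unequal amplitudes, linear shift-vs-indentation response,
blue/red shift signs by contact angle, side-contact attenuation, and a
stiff inclusion in a soft field. It does **not** model dome mechanics
(finite-element or Hertzian contact), viscoelasticity, temperature drift,
operator variability in press depth, or amplitude losses under large
deformation. Passing the recovery tests therefore shows the *pipeline* is
correct and robust at realistic signal levels — not that the physical probe
achieves these numbers on real tissue.

## Validation study sizes

The shipped tests run entirely on synthetic data built at test time: the
localization Monte-Carlo uses 1000 trials on a 2 nm sub-grid; the oracle
comparison 100 random centers on the full 80 nm sweep; inclusion recovery
20 seeded sessions of a 5 × 5 press lattice over the default phantom,
requiring the map argmax within one lattice spacing (8 mm) of the true
centroid in at least 90% of runs; the direct-vs-side contrast is asserted
at 10× ± 20% through the full fit pipeline at 1% noise. These sizes give
stable statistics while keeping the whole suite in a few minutes on one
core.

## Known limitations

* Relative stiffness only: no calibration to elastic modulus (kPa) exists,
  and none is provided.
* The four-channel vectorial information (force magnitude and direction) is
  deliberately not decoded; the statistic discards sign and direction.
* Session scores are not comparable across organs or scans.
* Probe-tip coordinates are inputs; image-based tip localization is out of
  scope.
* The nominal wavelengths, peak width and noise level are documented
  stand-ins for instrument characteristics that vary between probes; they
  are configurable wherever they appear.
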
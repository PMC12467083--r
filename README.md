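# palpmap

Stiffness mapping for fiber Bragg grating (FBG) palpation probes.

Minimally invasive surgery removes the surgeon's sense of touch: there is no
direct way to feel whether tissue under an endoscope is soft parenchyma or a
hard mass. One answer is an endoscopic palpation probe — an elastic silicone
dome with four FBGs embedded at 90° spacing that deforms on tissue contact.
Pressing the dome into tissue strains the gratings and shifts their Bragg
wavelengths; stiffer tissue deforms the dome more and shifts the peaks
further. `palpmap` implements the complete computational pipeline behind such
a probe, plus a forward simulator of palpation sessions over tissue phantoms
with embedded rigid inclusions, so the whole method can be developed and
validated without hardware.

## The method

For each press point the interrogator records two reflection spectra on a
2 pm wavelength grid: one at first contact, one after a fixed ~2 mm
indentation. For each of the four channels `i`, the spectrum is windowed
around the grating's nominal wavelength and a Gaussian-plus-baseline model is
fitted by bounded Levenberg–Marquardt least squares; the fitted center is the
Bragg wavelength λ_B,i, localized far below the hardware grid spacing. The
per-channel shift between the pressed and contact acquisition is

    Δλ_B,i = λ_B,i(pressed) − λ_B,i(contact)      [pm, signed]

and the per-point relative-stiffness statistic is the non-vectorial sum

    S = Σ_{i=1..4} |Δλ_B,i|                        [pm]

Within one session (one organ scan) the statistic is min–max normalized,

    s_norm = (S − S_min) / (S_max − S_min) ∈ [0, 1],

so the stiffest point scores exactly 1 and the softest exactly 0. The
normalized scores at their press coordinates are interpolated
(piecewise-linear on the Delaunay triangulation, nearest-neighbour outside
the convex hull) into a stiffness heat map, and connected regions above a
threshold fraction of the maximum localize hard inclusions under the
surface.

## Worked example

Simulate a palpation session over a 40 mm × 40 mm liver-like phantom with a
rigid blade (30× background stiffness) lying along y = 20 mm, pressed on a
3 × 3 lattice, then run the full pipeline:

```r
library(palpmap)

ph <- phantom_field(roi = c(40, 40), background = 1,
                    inclusion = list(x0 = 10, y0 = 20, x1 = 30, y1 = 20,
                                     half_width_mm = 2, multiplier = 30,
                                     depth_attenuation = 1))
proto <- palpation_protocol(lattice_points(ph, n = 3),
                            press_depth_mm = 2, seed = 42)
ses <- simulate_session(ph, proto, noise = noise_model(0.01))
res <- run_pipeline(ses, run_config(n_grid = 50))

res$records[, c("point_id", "x_rel", "y_rel", "S_pm", "s_norm")]
#> point_id x_rel y_rel     S_pm s_norm
#>        1     4     4   39.978  0.001
#>        2    20     4   40.146  0.001
#>        3    36     4   40.167  0.001
#>        4     4    20  120.300  0.070
#>        5    20    20 1199.439  1.000
#>        6    36    20  120.548  0.070
#>        7     4    36   39.647  0.000
#>        8    20    36   39.301  0.000
#>        9    36    36   40.574  0.001

res$regions
#> region_id centroid_x centroid_y  xmin  xmax  ymin  ymax n_cells area_fraction max_value
#>         1         20      19.98 11.84 28.16 11.84 28.16     505           0.2      0.98
```

Reading the output: plain parenchyma presses sum to ~40 pm of total Bragg
shift (four channels × ~10 pm at 2 mm indentation). The two presses beside
the blade sense it laterally through the flank of the dome at about a tenth
of the direct response (~120 pm), and the press directly over the blade reads
~1200 pm — an order of magnitude above side contact — so it alone saturates
the normalized score at 1. The detected stiff region is centered at
(20, 20.0) mm, the true blade centroid. `render_map(res$map, "scan")` writes
the heat-map matrix as CSV plus a red-high/blue-low PNG;
`run_pipeline(..., out_dir = "out")` writes the stiffness table, map and
region summary together. A command-line front end with
`simulate` / `fit` / `score` / `map` / `run` subcommands is in
`inst/cli/palpmap.R`.

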
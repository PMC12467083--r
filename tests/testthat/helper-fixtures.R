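# Shared fixtures: compact grids and channel layouts so most tests avoid the
# full 80 nm sweep, plus the independent localization oracle.

# single-channel layout with unit effective amplitude
one_channel <- function(center_nm = 1540) {
  bragg_channels(center_nm, azimuth_deg = 0, reflectivity = 1)
}

# 2 pm grid spanning [center - half_nm, center + half_nm]
narrow_grid <- function(center_nm = 1540, half_nm = 1) {
  n <- round(2 * half_nm / 0.002) + 1
  wavelength_grid(center_nm - half_nm, 2, n)
}

# four-channel layout on a reduced sweep (1530-1550 nm) for fast end-to-end
# tests; 2 pm step like the full instrument
fast_channels <- function() {
  bragg_channels(c(1534, 1538, 1542, 1546))
}

fast_grid <- function() wavelength_grid(1530, 2, 10001L)

quiet_noise <- function() noise_model(0)

# Independent localization oracle: render the same Gaussian (no baseline) on
# a 100x oversampled grid and take the vertex of the parabola through the
# three log-intensity samples around the argmax. For a pure Gaussian the
# log-intensity is exactly parabolic, so this recovers the center without any
# curve fitting.
oracle_center <- function(true_center_nm, fwhm_pm, grid, amplitude = 1) {
  step <- grid$step_pm * 1e-3 / 100
  wl <- seq(grid$start_nm, grid$start_nm + (grid$n_points - 1) * grid$step_pm * 1e-3,
            by = step)
  s <- (fwhm_pm / (2 * sqrt(2 * log(2)))) * 1e-3
  inten <- amplitude * exp(-(wl - true_center_nm)^2 / (2 * s^2))
  i <- which.max(inten)
  i <- min(max(i, 2L), length(wl) - 1L)
  ly <- log(inten[(i - 1):(i + 1)])
  # vertex of the parabola through (-1, 0, +1) * step
  delta <- 0.5 * (ly[1] - ly[3]) / (ly[1] - 2 * ly[2] + ly[3])
  wl[i] + delta * step
}

# default inclusion phantom used across simulator tests: horizontal blade
# along y = 20 mm, x in [10, 30] mm
blade_phantom <- function(multiplier = 30, depth_attenuation = 1,
                          half_width_mm = 2) {
  phantom_field(
    roi = c(40, 40), background = 1,
    inclusion = list(x0 = 10, y0 = 20, x1 = 30, y1 = 20,
                     half_width_mm = half_width_mm,
                     multiplier = multiplier,
                     depth_attenuation = depth_attenuation)
  )
}

# records helper for map tests
grid_records <- function(xs, ys, values) {
  pts <- expand.grid(x = xs, y = ys)
  r <- stiffness_records(seq_len(nrow(pts)), pts$x, pts$y,
                         lapply(values, function(v) c(v, 0, 0, 0)))
  r$s_norm <- values
  r
}
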
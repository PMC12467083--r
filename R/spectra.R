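#' Uniform wavelength grid of an FBG interrogator sweep
#'
#' The interrogator samples the fiber's reflection spectrum on a uniform
#' wavelength grid. The grid is stored by its start, step and length so that
#' node positions are reproducible to machine precision (`start + step * k`),
#' avoiding cumulative rounding over wide sweeps.
#'
#' @param start_nm first wavelength of the sweep, in nm.
#' @param step_pm grid spacing, in pm (the hardware spectral resolution;
#'   default 2 pm).
#' @param n_points number of samples (at least 16).
#' @return An object of class `wavelength_grid`.
#' @examples
#' g <- wavelength_grid(1510, 2, 40001)  # 1510-1590 nm at 2 pm
#' range(wavelengths(g))
#' @export
wavelength_grid <- function(start_nm, step_pm = 2, n_points = 40001L) {
  stopifnot(is.numeric(start_nm), length(start_nm) == 1L, is.finite(start_nm))
  if (!is.numeric(step_pm) || length(step_pm) != 1L || !is.finite(step_pm) ||
      step_pm <= 0) {
    stop("`step_pm` must be a single positive number")
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 16L) {
    stop("`n_points` must be an integer >= 16")
  }
  structure(
    list(start_nm = as.numeric(start_nm), step_pm = as.numeric(step_pm),
         n_points = n_points),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %.6f-%.6f nm, step %g pm, %d points\n",
              x$start_nm, grid_end_nm(x), x$step_pm, x$n_points))
  invisible(x)
}

#' Wavelength nodes of a grid
#'
#' @param grid a [wavelength_grid()].
#' @return Numeric vector of wavelengths in nm, strictly increasing.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + grid$step_pm * 1e-3 * (seq_len(grid$n_points) - 1)
}

grid_end_nm <- function(grid) {
  grid$start_nm + grid$step_pm * 1e-3 * (grid$n_points - 1)
}

#' Four-channel Bragg grating layout of the probe dome
#'
#' The probe carries four FBGs placed symmetrically around the hemispherical
#' dome at 90 degree angular spacing. Each channel is identified by its nominal
#' (unstrained) Bragg wavelength; channels are wavelength-multiplexed on one
#' fiber, so nominal centers must be strictly increasing with channel id.
#'
#' @param nominal_center_nm nominal Bragg wavelengths in nm, strictly
#'   increasing (default four C-band peaks at 1520/1540/1560/1580 nm).
#' @param azimuth_deg angular position of each FBG on the dome, degrees;
#'   must be distinct multiples of 90.
#' @param reflectivity peak reflectivity of each grating, in (0, 1]
#'   (default 0.3, recycled).
#' @param fiber_position_mm position of each grating along the fiber, mm.
#'   Defaults to the paired layout (15 mm within a pair, 100 mm between pairs).
#' @return A data frame of class `bragg_channels` with one row per channel.
#' @examples
#' bragg_channels()
#' @export
bragg_channels <- function(nominal_center_nm = c(1520, 1540, 1560, 1580),
                           azimuth_deg = c(0, 90, 180, 270),
                           reflectivity = 0.3,
                           fiber_position_mm = c(0, 15, 115, 130)) {
  n <- length(nominal_center_nm)
  if (n < 1L) stop("at least one channel is required")
  if (any(!is.finite(nominal_center_nm)) ||
      any(diff(nominal_center_nm) <= 0)) {
    stop("nominal centers must be finite and strictly increasing with channel id")
  }
  if (length(azimuth_deg) != n || anyDuplicated(azimuth_deg) ||
      any(azimuth_deg %% 90 != 0)) {
    stop("azimuths must be distinct multiples of 90 degrees, one per channel")
  }
  reflectivity <- rep_len(reflectivity, n)
  if (any(reflectivity <= 0 | reflectivity > 1)) {
    stop("reflectivity must lie in (0, 1]")
  }
  fiber_position_mm <- rep_len(fiber_position_mm, n)
  structure(
    data.frame(
      channel_id = seq_len(n),
      nominal_center_nm = as.numeric(nominal_center_nm),
      azimuth_deg = as.numeric(azimuth_deg),
      reflectivity = reflectivity,
      fiber_position_mm = as.numeric(fiber_position_mm)
    ),
    class = c("bragg_channels", "data.frame")
  )
}

#' Additive white-noise model for synthesized spectra
#'
#' @param sigma_rel standard deviation of the additive Gaussian intensity
#'   noise, as a fraction of the tallest peak amplitude (default 0.01).
#' @param seed optional RNG seed; with a seed the synthesized noise is
#'   bit-reproducible and the caller's RNG state is left untouched.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0.01, seed = NULL) {
  if (!is.numeric(sigma_rel) || length(sigma_rel) != 1L ||
      !is.finite(sigma_rel) || sigma_rel < 0) {
    stop("`sigma_rel` must be a single number >= 0")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(sigma_rel = sigma_rel, seed = seed), class = "noise_model")
}

#' A single interrogation frame
#'
#' @param grid a [wavelength_grid()].
#' @param intensity non-negative intensity vector (arbitrary units), one value
#'   per grid node.
#' @param timestamp optional acquisition tag.
#' @return An object of class `fbg_spectrum`.
#' @export
fbg_spectrum <- function(grid, intensity, timestamp = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"))
  intensity <- as.numeric(intensity)
  if (length(intensity) != grid$n_points) {
    stop(sprintf("intensity length (%d) must equal the grid length (%d)",
                 length(intensity), grid$n_points))
  }
  if (any(!is.finite(intensity))) stop("intensity must be finite everywhere")
  if (any(intensity < 0)) stop("intensity must be non-negative")
  structure(list(grid = grid, intensity = intensity, timestamp = timestamp),
            class = "fbg_spectrum")
}

#' @export
print.fbg_spectrum <- function(x, ...) {
  cat(sprintf("<fbg_spectrum> %d samples, %.4f-%.4f nm, max intensity %.4g\n",
              x$grid$n_points, x$grid$start_nm, grid_end_nm(x$grid),
              max(x$intensity)))
  invisible(x)
}

#' Linear source-envelope gain ramp
#'
#' The interrogator's optical power output is not flat across the sweep: it
#' rises towards the red end, so gratings with similar reflectivity still show
#' unequal peak amplitudes. This helper builds the default gain profile, a
#' linear ramp across a grid span.
#'
#' @param grid a [wavelength_grid()] giving the span the ramp covers.
#' @param gain_lo,gain_hi gain at the blue and red end of the grid.
#' @return A function of wavelength (nm) returning the gain.
#' @export
ramp_envelope <- function(grid, gain_lo = 0.4, gain_hi = 1) {
  stopifnot(inherits(grid, "wavelength_grid"))
  lo <- grid$start_nm
  hi <- grid_end_nm(grid)
  force(gain_lo); force(gain_hi)
  function(wl_nm) gain_lo + (gain_hi - gain_lo) * (wl_nm - lo) / (hi - lo)
}

#' Flat (identity) source envelope
#' @return A function of wavelength returning gain 1 everywhere.
#' @export
flat_envelope <- function() function(wl_nm) rep(1, length(wl_nm))

# Run `expr` with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Synthesize a four-peak Bragg reflection spectrum
#'
#' Forward model of one interrogation frame: a sum of Gaussian reflection
#' peaks, one per channel, each scaled by the channel reflectivity and by the
#' source envelope evaluated at the peak center, on top of a constant detector
#' floor, plus additive white Gaussian noise (clipped at zero, since measured
#' intensity cannot be negative).
#'
#' @param channels a [bragg_channels()] layout.
#' @param centers_nm current Bragg wavelength of each channel, nm (defaults to
#'   the nominal centers). Each must lie inside the grid span.
#' @param grid a [wavelength_grid()].
#' @param envelope source envelope function wavelength (nm) -> gain, or `NULL`
#'   for the default red-rising [ramp_envelope()] over the grid.
#' @param noise a [noise_model()]; `sigma_rel` is interpreted relative to the
#'   tallest effective peak amplitude.
#' @param fwhm_pm full width at half maximum of each reflection peak, pm
#'   (default 60), recycled per channel.
#' @param baseline constant detector floor added to the signal (default 0.02).
#' @param timestamp optional acquisition tag stored on the spectrum.
#' @return An [fbg_spectrum()].
#' @examples
#' sp <- synth_spectrum(bragg_channels(), noise = noise_model(0, seed = 1))
#' max(sp$intensity)
#' @export
synth_spectrum <- function(channels,
                           centers_nm = channels$nominal_center_nm,
                           grid = wavelength_grid(1510, 2, 40001L),
                           envelope = NULL,
                           noise = noise_model(),
                           fwhm_pm = 60,
                           baseline = 0.02,
                           timestamp = NULL) {
  stopifnot(inherits(channels, "bragg_channels"),
            inherits(grid, "wavelength_grid"),
            inherits(noise, "noise_model"))
  n_ch <- nrow(channels)
  if (length(centers_nm) != n_ch) {
    stop("`centers_nm` must supply one center per channel")
  }
  lo <- grid$start_nm
  hi <- grid_end_nm(grid)
  bad <- which(centers_nm <= lo | centers_nm >= hi)
  if (length(bad)) {
    stop(sprintf("center of channel %s lies outside the grid span [%g, %g] nm",
                 paste(channels$channel_id[bad], collapse = ", "), lo, hi))
  }
  fwhm_pm <- rep_len(fwhm_pm, n_ch)
  if (any(fwhm_pm <= 0)) stop("`fwhm_pm` must be positive")
  if (is.null(envelope)) envelope <- ramp_envelope(grid)

  wl <- wavelengths(grid)
  intensity <- rep(baseline, grid$n_points)
  amp <- channels$reflectivity * envelope(centers_nm)
  sigma_nm <- fwhm_to_sigma(fwhm_pm) * 1e-3
  for (i in seq_len(n_ch)) {
    intensity <- intensity +
      amp[i] * exp(-(wl - centers_nm[i])^2 / (2 * sigma_nm[i]^2))
  }
  if (noise$sigma_rel > 0) {
    sd_abs <- noise$sigma_rel * max(amp)
    eps <- with_local_seed(noise$seed, stats::rnorm(grid$n_points, 0, sd_abs))
    intensity <- pmax(intensity + eps, 0)
  }
  fbg_spectrum(grid, intensity, timestamp = timestamp)
}

#' Read a spectrum from a two-column text file
#'
#' Accepts the interrogator dump format: UTF-8 text, comma- or tab-separated,
#' columns `wavelength_nm,intensity`, with one optional header line. The
#' wavelength column must form a strictly increasing uniform grid; intensities
#' must be non-negative and finite.
#'
#' @param path file to read.
#' @return An [fbg_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop(sprintf("spectrum file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("spectrum file is empty: %s", path))

  parse_line <- function(ln) strsplit(trimws(ln), "[,\t]")[[1]]
  first <- suppressWarnings(as.numeric(parse_line(lines[[1]])))
  start_row <- if (any(is.na(first))) 2L else 1L
  if (start_row > length(lines)) {
    stop(sprintf("spectrum file has a header but no data rows: %s", path))
  }

  data_lines <- lines[start_row:length(lines)]
  n <- length(data_lines)
  sep <- if (grepl("\t", data_lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(trimws(data_lines), sep, fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short)) {
    stop(sprintf("line %d of %s: expected two numeric columns (wavelength_nm, intensity)",
                 start_row + short[1L] - 1L, path))
  }
  wl <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(is.na(wl) | is.na(it))
  if (length(bad)) {
    stop(sprintf("line %d of %s: expected two numeric columns (wavelength_nm, intensity)",
                 start_row + bad[1L] - 1L, path))
  }
  if (n < 16L) {
    stop(sprintf("%s: %d samples; a spectrum needs at least 16", path, n))
  }
  d <- diff(wl)
  if (any(d <= 0)) {
    k <- which(d <= 0)[1L]
    stop(sprintf("line %d of %s: wavelengths are not strictly increasing",
                 start_row + k, path))
  }
  step <- (wl[n] - wl[1L]) / (n - 1L)
  if (max(abs(d - step)) > 1e-6 * step) {
    k <- which.max(abs(d - step))
    stop(sprintf("line %d of %s: wavelength grid is not uniform",
                 start_row + k, path))
  }
  neg <- which(it < 0)
  if (length(neg)) {
    stop(sprintf("line %d of %s: negative intensity", start_row + neg[1L] - 1L, path))
  }
  fbg_spectrum(wavelength_grid(wl[1L], step * 1e3, n), it)
}

#' Write a spectrum to a two-column text file
#'
#' Values are written with 12 significant digits so a write/read round trip
#' preserves them to better than 1e-9 relative.
#'
#' @param spectrum an [fbg_spectrum()].
#' @param path destination file.
#' @param sep column separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, sep = ",") {
  stopifnot(inherits(spectrum, "fbg_spectrum"))
  wl <- wavelengths(spectrum$grid)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("wavelength_nm", "intensity", sep = sep), con)
  writeLines(paste(sprintf("%.12g", wl), sprintf("%.12g", spectrum$intensity),
                   sep = sep), con)
  invisible(path)
}
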
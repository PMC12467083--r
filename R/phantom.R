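#' Tissue phantom: a 2D relative-stiffness field with an optional inclusion
#'
#' Abstraction of the bench experiment in which a metallic blade (scalpel or
#' stitching needle) is slid underneath a marked area of liver parenchyma:
#' a uniform soft background with a stiff line segment embedded in it. The
#' inclusion raises the local stiffness by a multiplier, attenuated by how
#' deep it sits under the surface, with a continuous taper at its edge.
#'
#' @param roi region of interest `c(width_mm, height_mm)` (default 40 x 40,
#'   origin at the lower-left corner, x right, y up).
#' @param background relative stiffness of the parenchyma (default 1).
#' @param inclusion `NULL` for a uniform phantom, or a list with `x0, y0,
#'   x1, y1` (segment endpoints, mm), `half_width_mm`, `multiplier`
#'   (stiffness ratio of the object to background) and `depth_attenuation`
#'   (in (0, 1]; 1 = object directly under the surface).
#' @param taper_mm width of the continuous edge taper beyond the half-width
#'   (default equal to `half_width_mm`).
#' @return An object of class `phantom_field`.
#' @examples
#' ph <- phantom_field(inclusion = list(x0 = 10, y0 = 20, x1 = 30, y1 = 20,
#'                                      half_width_mm = 2, multiplier = 30,
#'                                      depth_attenuation = 1))
#' local_stiffness(ph, 20, 20)  # on the blade axis
#' local_stiffness(ph, 20, 5)   # plain parenchyma
#' @export
phantom_field <- function(roi = c(40, 40), background = 1,
                          inclusion = NULL, taper_mm = NULL) {
  stopifnot(length(roi) == 2L, all(roi > 0))
  if (background <= 0) stop("stiffness values must be positive")
  if (!is.null(inclusion)) {
    need <- c("x0", "y0", "x1", "y1", "half_width_mm", "multiplier",
              "depth_attenuation")
    missing <- setdiff(need, names(inclusion))
    if (length(missing)) {
      stop(sprintf("inclusion is missing fields: %s",
                   paste(missing, collapse = ", ")))
    }
    with(inclusion, {
      if (half_width_mm <= 0) stop("inclusion half-width must be positive")
      if (multiplier <= 0) stop("inclusion multiplier must be positive")
      if (depth_attenuation <= 0 || depth_attenuation > 1) {
        stop("depth_attenuation must lie in (0, 1]")
      }
      if (any(c(x0, x1) < 0 | c(x0, x1) > roi[1]) ||
          any(c(y0, y1) < 0 | c(y0, y1) > roi[2])) {
        stop("inclusion endpoints must lie inside the roi")
      }
    })
    if (is.null(taper_mm)) taper_mm <- inclusion$half_width_mm
  } else if (is.null(taper_mm)) {
    taper_mm <- 0
  }
  structure(list(roi = as.numeric(roi), background = background,
                 inclusion = inclusion, taper_mm = taper_mm),
            class = "phantom_field")
}

# distance from (x, y) to the inclusion axis segment
segment_distance <- function(inc, x, y) {
  vx <- inc$x1 - inc$x0
  vy <- inc$y1 - inc$y0
  len2 <- vx^2 + vy^2
  t <- if (len2 > 0) ((x - inc$x0) * vx + (y - inc$y0) * vy) / len2 else 0
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (inc$x0 + t * vx))^2 + (y - (inc$y0 + t * vy))^2)
}

#' Local relative stiffness of a phantom
#'
#' Background stiffness everywhere, elevated to
#' `background * multiplier * depth_attenuation` within the inclusion
#' half-width, with a smooth cosine taper back to background over
#' `taper_mm` beyond the edge.
#'
#' @param field a [phantom_field()].
#' @param x,y query coordinates (mm); must lie inside the roi.
#' @return Relative stiffness value(s).
#' @export
local_stiffness <- function(field, x, y) {
  stopifnot(inherits(field, "phantom_field"))
  stopifnot(length(x) == length(y))
  if (any(x < 0 | x > field$roi[1] | y < 0 | y > field$roi[2])) {
    stop("query point lies outside the phantom roi")
  }
  bg <- field$background
  inc <- field$inclusion
  if (is.null(inc)) return(rep(bg, length(x)))
  peak <- bg * inc$multiplier * inc$depth_attenuation
  d <- segment_distance(inc, x, y)
  w <- numeric(length(d))
  w[d <= inc$half_width_mm] <- 1
  tp <- field$taper_mm
  if (tp > 0) {
    mid <- d > inc$half_width_mm & d < inc$half_width_mm + tp
    w[mid] <- 0.5 * (1 + cos(pi * (d[mid] - inc$half_width_mm) / tp))
  }
  bg + (peak - bg) * w
}

#' Palpation protocol: where and how the probe presses
#'
#' @param points two-column matrix or data frame of press coordinates
#'   `(x, y)` in mm, in acquisition order.
#' @param press_depth_mm indentation between the contact and pressed
#'   acquisitions (default 2 mm, the depth enforced by a mechanical limiter
#'   in practice).
#' @param response_slope mean per-FBG Bragg shift per mm of indentation per
#'   unit relative stiffness, pm/mm (default 5, so a 2 mm press on
#'   background tissue shifts each channel by ~10 pm — far above the
#'   localization floor, far below the large-deformation regime).
#' @param side_contact_attenuation factor applied to the inclusion response
#'   when the probe presses beside the stiff object rather than directly over
#'   it (default 0.1: side contact reads about an order of magnitude weaker).
#' @param influence_radius_mm how far from the inclusion axis a side contact
#'   still senses it (default 8 mm, about a probe radius beyond the dome).
#' @param seed RNG seed for the session's noise realizations.
#' @return An object of class `palpation_protocol`.
#' @export
palpation_protocol <- function(points, press_depth_mm = 2,
                               response_slope = 5,
                               side_contact_attenuation = 0.1,
                               influence_radius_mm = 8,
                               seed = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || !nrow(points)) {
    stop("`points` must be a non-empty two-column (x, y) matrix")
  }
  if (press_depth_mm < 0) stop("press depth must be >= 0")
  if (response_slope <= 0) stop("response slope must be positive")
  if (side_contact_attenuation <= 0 || side_contact_attenuation > 1) {
    stop("side-contact attenuation must lie in (0, 1]")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(points = unname(points), press_depth_mm = press_depth_mm,
         response_slope = response_slope,
         side_contact_attenuation = side_contact_attenuation,
         influence_radius_mm = influence_radius_mm, seed = seed),
    class = "palpation_protocol"
  )
}

#' Regular press-point lattice over a phantom
#'
#' @param field a [phantom_field()].
#' @param n points per axis (default 5).
#' @param margin_mm margin kept from the roi border (default 4).
#' @return A two-column matrix of press coordinates in row-major order.
#' @export
lattice_points <- function(field, n = 5, margin_mm = 4) {
  stopifnot(inherits(field, "phantom_field"))
  xs <- seq(margin_mm, field$roi[1] - margin_mm, length.out = n)
  ys <- seq(margin_mm, field$roi[2] - margin_mm, length.out = n)
  cbind(x = rep(xs, times = n), y = rep(ys, each = n))
}

# Effective stiffness sensed by a press, and the lateral contact geometry.
# Direct contact (within the tapered inclusion footprint) senses the local
# field; side contact within the influence radius senses the hard object
# through the flank of the dome, attenuated by side_contact_attenuation
# (never below background); beyond the influence radius only background.
sensed_stiffness <- function(field, protocol, x, y) {
  bg <- field$background
  inc <- field$inclusion
  if (is.null(inc)) {
    return(list(stiffness = bg, mode = "background", offset_dir = c(0, 0)))
  }
  d <- segment_distance(inc, x, y)
  direct_extent <- inc$half_width_mm + field$taper_mm
  peak <- bg * inc$multiplier * inc$depth_attenuation
  if (d <= direct_extent) {
    list(stiffness = local_stiffness(field, x, y), mode = "direct",
         offset_dir = c(0, 0))
  } else if (d <= protocol$influence_radius_mm) {
    # unit vector from the press point towards the inclusion axis
    t_num <- (x - inc$x0) * (inc$x1 - inc$x0) + (y - inc$y0) * (inc$y1 - inc$y0)
    len2 <- (inc$x1 - inc$x0)^2 + (inc$y1 - inc$y0)^2
    t <- if (len2 > 0) min(max(t_num / len2, 0), 1) else 0
    px <- inc$x0 + t * (inc$x1 - inc$x0)
    py <- inc$y0 + t * (inc$y1 - inc$y0)
    u <- c(px - x, py - y) / d
    list(stiffness = max(bg, peak * protocol$side_contact_attenuation),
         mode = "side", offset_dir = u)
  } else {
    list(stiffness = bg, mode = "background", offset_dir = c(0, 0))
  }
}

# Per-channel sign pattern of the press. Centered (direct/background)
# contact loads all four gratings alike: the dome flattens and every FBG
# sees tension (red-shift). A side contact bends the dome towards the hard
# object: the FBG pair along the offset axis splits into tension on the near
# side and compression (blue-shift) on the far side.
direction_weights <- function(channels, mode, offset_dir) {
  if (mode != "side" || all(offset_dir == 0)) {
    return(rep(1, nrow(channels)))
  }
  phi <- atan2(offset_dir[2], offset_dir[1])
  theta <- channels$azimuth_deg * pi / 180
  ifelse(cos(theta - phi) >= 0, 1, -1)
}

#' Simulate one press: a contact/pressed spectrum pair
#'
#' Forward model of one palpation measurement. The contact spectrum is
#' synthesized at the nominal Bragg wavelengths (first touch, no load); the
#' pressed spectrum applies per-channel shifts
#' `response_slope * press_depth * sensed stiffness * direction weight`,
#' where the sensed stiffness and the sign pattern depend on whether the
#' press lands directly over the inclusion, beside it (side contact, about
#' an order of magnitude weaker), or on plain background.
#'
#' @param field a [phantom_field()].
#' @param protocol a [palpation_protocol()].
#' @param channels a [bragg_channels()] layout.
#' @param grid a [wavelength_grid()].
#' @param noise a [noise_model()]; its `seed` (if any) makes the pair
#'   reproducible.
#' @param x,y press coordinates (mm).
#' @return A list with `contact` and `pressed` [fbg_spectrum()]s, the
#'   noiseless `true_shifts_pm` vector, and the contact `mode`.
#' @export
simulate_press <- function(field, protocol, channels,
                           grid = wavelength_grid(1510, 2, 40001L),
                           noise = noise_model(), x, y) {
  stopifnot(inherits(field, "phantom_field"),
            inherits(protocol, "palpation_protocol"),
            inherits(channels, "bragg_channels"))
  if (protocol$press_depth_mm < 0) stop("press depth must be >= 0")
  sensed <- sensed_stiffness(field, protocol, x, y)
  w <- direction_weights(channels, sensed$mode, sensed$offset_dir)
  shifts_pm <- protocol$response_slope * protocol$press_depth_mm *
    sensed$stiffness * w

  seed_contact <- if (is.null(noise$seed)) NULL else noise$seed
  seed_pressed <- if (is.null(noise$seed)) NULL else (noise$seed + 1L) %% .Machine$integer.max
  contact <- synth_spectrum(channels, grid = grid,
                            noise = noise_model(noise$sigma_rel, seed_contact))
  pressed <- synth_spectrum(channels,
                            centers_nm = channels$nominal_center_nm +
                              shifts_pm * 1e-3,
                            grid = grid,
                            noise = noise_model(noise$sigma_rel, seed_pressed))
  list(contact = contact, pressed = pressed, true_shifts_pm = shifts_pm,
       mode = sensed$mode)
}

#' Simulate a full palpation session over a phantom
#'
#' One contact/pressed spectrum pair per protocol point. With `dir` set, the
#' spectra are written as two-column text files and a JSON session manifest
#' referencing them is written alongside — the same format [run_pipeline()]
#' consumes — so a simulated session is a drop-in replacement for a recorded
#' one. Fully reproducible from the protocol seed.
#'
#' @inheritParams simulate_press
#' @param dir optional directory for the session files (created if missing).
#' @param session_id identifier stored in the manifest.
#' @return An object of class `palpation_session`: `session_id`, `roi`,
#'   a `points` data frame (`point_id`, `x_rel`, `y_rel`, contact/pressed
#'   spectra or file names, `true_S_pm`, `mode`), `manifest` (path or `NULL`)
#'   and `seed`.
#' @export
simulate_session <- function(field, protocol, channels = bragg_channels(),
                             grid = wavelength_grid(1510, 2, 40001L),
                             noise = noise_model(), dir = NULL,
                             session_id = "phantom-session") {
  stopifnot(inherits(field, "phantom_field"),
            inherits(protocol, "palpation_protocol"))
  n <- nrow(protocol$points)
  base_seed <- protocol$seed
  write_files <- !is.null(dir)
  if (write_files && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }

  rows <- vector("list", n)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    xy <- protocol$points[i, ]
    pt_seed <- if (is.null(base_seed)) NULL else
      (base_seed + 2L * (i - 1L)) %% .Machine$integer.max
    press <- simulate_press(field, protocol, channels, grid,
                            noise_model(noise$sigma_rel, pt_seed),
                            xy[1], xy[2])
    contact_ref <- pressed_ref <- NA_character_
    if (write_files) {
      contact_ref <- sprintf("point%02d_contact.csv", i)
      pressed_ref <- sprintf("point%02d_pressed.csv", i)
      write_spectrum(press$contact, file.path(dir, contact_ref))
      write_spectrum(press$pressed, file.path(dir, pressed_ref))
    }
    spectra[[i]] <- press
    rows[[i]] <- data.frame(
      point_id = i, x_rel = xy[1], y_rel = xy[2],
      contact = contact_ref, pressed = pressed_ref,
      true_S_pm = sum(abs(press$true_shifts_pm)),
      mode = press$mode
    )
  }
  points <- do.call(rbind, rows)

  manifest <- NULL
  if (write_files) {
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(schema_version = 1L,
           session_id = session_id,
           roi = list(width_mm = field$roi[1], height_mm = field$roi[2]),
           seed = if (is.null(base_seed)) NA else base_seed,
           points = points[, c("point_id", "x_rel", "y_rel",
                               "contact", "pressed")]),
      manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(session_id = session_id, roi = field$roi, points = points,
         spectra = spectra, manifest = manifest, seed = base_seed),
    class = "palpation_session"
  )
}

#' @export
print.palpation_session <- function(x, ...) {
  cat(sprintf("<palpation_session> %s: %d points over %g x %g mm%s\n",
              x$session_id, nrow(x$points), x$roi[1], x$roi[2],
              if (is.null(x$manifest)) "" else paste0(" (", x$manifest, ")")))
  invisible(x)
}
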
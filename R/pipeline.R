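#' Pipeline run configuration
#'
#' Collects everything the end-to-end pipeline needs beyond the session
#' manifest itself, validated up front so a bad configuration fails before
#' any stage runs.
#'
#' @param channels a [bragg_channels()] layout (default four-channel probe).
#' @param fwhm_pm initial Gaussian width for the peak fits, pm.
#' @param resolution output map grid spacing, mm, or `NULL` for `n_grid`.
#' @param n_grid output map nodes per axis when `resolution` is `NULL`.
#' @param threshold stiff-region threshold as a fraction of the map maximum.
#' @param normalization_scope `"session"`: the only supported scope —
#'   relative stiffness is normalized within one session.
#' @param seed seed recorded with the run (simulation stages draw their
#'   randomness from it).
#' @param verbose emit per-stage log messages.
#' @return A validated object of class `run_config`.
#' @export
run_config <- function(channels = bragg_channels(), fwhm_pm = 60,
                       resolution = NULL, n_grid = 50, threshold = 0.5,
                       normalization_scope = "session",
                       seed = NULL, verbose = FALSE) {
  cfg <- structure(
    list(channels = channels, fwhm_pm = fwhm_pm, resolution = resolution,
         n_grid = n_grid, threshold = threshold,
         normalization_scope = normalization_scope,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "run_config"
  )
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` (or plain list with the same fields).
#' @return The validated config, invisibly classed `run_config`; invalid
#'   configurations fail with a field-level message.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  if (!inherits(cfg$channels, "bragg_channels")) {
    problems <- c(problems, "channels: must be a bragg_channels() layout")
  }
  if (!is.numeric(cfg$fwhm_pm) || length(cfg$fwhm_pm) != 1L ||
      cfg$fwhm_pm <= 0) {
    problems <- c(problems, "fwhm_pm: must be a single positive number")
  }
  if (!is.null(cfg$resolution) &&
      (!is.numeric(cfg$resolution) || cfg$resolution <= 0)) {
    problems <- c(problems, "resolution: must be NULL or a positive number")
  }
  if (!is.numeric(cfg$n_grid) || length(cfg$n_grid) != 1L || cfg$n_grid < 2) {
    problems <- c(problems, "n_grid: must be an integer >= 2")
  }
  if (!is.numeric(cfg$threshold) || length(cfg$threshold) != 1L ||
      cfg$threshold < 0) {
    problems <- c(problems, "threshold: must be a single number >= 0")
  }
  if (!identical(cfg$normalization_scope, "session")) {
    problems <- c(problems, "normalization_scope: only \"session\" is supported")
  }
  if (length(problems)) {
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "))
  }
  invisible(structure(cfg, class = "run_config"))
}

#' Read a palpation session manifest
#'
#' @param path a JSON manifest as written by [simulate_session()]: fields
#'   `session_id`, `roi` (`width_mm`, `height_mm`) and `points` (each with
#'   `point_id`, `x_rel`, `y_rel`, `contact`, `pressed` spectrum file
#'   references relative to the manifest directory).
#' @return A list with `session_id`, `roi`, `points` (data frame) and `dir`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$points) || !nrow(as.data.frame(m$points))) {
    stop(sprintf("manifest %s lists no points", path))
  }
  pts <- as.data.frame(m$points)
  need <- c("point_id", "x_rel", "y_rel", "contact", "pressed")
  missing <- setdiff(need, names(pts))
  if (length(missing)) {
    stop(sprintf("manifest %s points are missing fields: %s",
                 path, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(pts$point_id)) {
    stop(sprintf("manifest %s has duplicate point ids", path))
  }
  list(session_id = m$session_id %||% "session",
       roi = c(m$roi$width_mm %||% NA_real_, m$roi$height_mm %||% NA_real_),
       points = pts, dir = dirname(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full measurement-to-map pipeline on a session
#'
#' For every press point of the manifest: read the contact and pressed
#' spectra, fit the four Bragg peaks in each, compute the per-channel shifts,
#' and accumulate the summed-absolute-shift statistic. The session is then
#' min-max normalized, interpolated into a stiffness heat map, and stiff
#' regions are located. Any point whose shifts cannot be computed (missing
#' file, unparseable spectrum, unconverged channel) aborts the run with an
#' error naming that point; a contrast-free session only warns.
#'
#' @param manifest path to a session manifest JSON (see [read_manifest()]),
#'   or an in-memory [simulate_session()] result.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when set, the stiffness table
#'   (`stiffness_table.csv`), map matrix + PNG (`map_values.csv`, `map.png`)
#'   and region summary (`regions.csv`) are written there.
#' @return A list with `records` (the normalized stiffness table), `map`
#'   (a [interpolate_map()] result), `regions`
#'   (a [detect_stiff_region()] summary), `fits` (per-point peak-fit
#'   diagnostics) and `paths` (written files, if any).
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir = NULL) {
  config <- validate_config(config)
  log_msg <- function(...) if (config$verbose) message(sprintf(...))

  if (inherits(manifest, "palpation_session")) {
    session <- list(session_id = manifest$session_id, roi = manifest$roi,
                    points = manifest$points, dir = NA_character_)
    get_pair <- function(i) manifest$spectra[[i]][c("contact", "pressed")]
  } else {
    session <- read_manifest(manifest)
    get_pair <- function(i) {
      row <- session$points[i, ]
      paths <- file.path(session$dir, c(row$contact, row$pressed))
      miss <- !file.exists(paths)
      if (any(miss)) {
        stop(sprintf("point %s: spectrum file missing: %s", row$point_id,
                     paste(paths[miss], collapse = ", ")))
      }
      list(contact = read_spectrum(paths[1]), pressed = read_spectrum(paths[2]))
    }
  }
  log_msg("session %s: %d points%s", session$session_id,
          nrow(session$points),
          if (is.null(config$seed)) "" else sprintf(", seed %d", config$seed))
  log_msg("config: %s", format_config(config))

  n <- nrow(session$points)
  shifts <- vector("list", n)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- session$points$point_id[i]
    res <- tryCatch({
      pair <- get_pair(i)
      ref <- extract_peaks(pair$contact, config$channels, config$fwhm_pm)
      prs <- extract_peaks(pair$pressed, config$channels, config$fwhm_pm)
      list(shift = compute_shifts(ref, prs), ref = ref, prs = prs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stop(sprintf("point %s: %s", pid, conditionMessage(res)))
    }
    shifts[[i]] <- res$shift
    fits[[i]] <- list(point_id = pid, contact = res$ref, pressed = res$prs)
    log_msg("point %s: shifts [%s] pm", pid,
            paste(sprintf("%+.2f", res$shift), collapse = ", "))
  }

  records <- stiffness_records(session$points$point_id,
                               session$points$x_rel, session$points$y_rel,
                               shifts)
  records <- normalize_session(records)
  map <- interpolate_map(records, resolution = config$resolution,
                         n_grid = config$n_grid)
  regions <- detect_stiff_region(map, config$threshold)
  log_msg("map: %d x %d grid, %d stiff region(s) at threshold %.2f",
          length(map$grid_x), length(map$grid_y), nrow(regions),
          config$threshold)

  paths <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    tab <- file.path(out_dir, "stiffness_table.csv")
    write_stiffness_table(records, tab)
    rendered <- render_map(map, file.path(out_dir, "map"))
    reg <- file.path(out_dir, "regions.csv")
    utils::write.csv(regions, reg, row.names = FALSE)
    paths <- c(stiffness_table = tab, rendered, regions = reg)
    log_msg("wrote %s", paste(paths, collapse = ", "))
  }
  list(records = records, map = map, regions = regions, fits = fits,
       paths = paths)
}

# one-line canonical rendering of a config, for logs
format_config <- function(cfg) {
  jsonlite::toJSON(
    list(centers_nm = cfg$channels$nominal_center_nm,
         fwhm_pm = cfg$fwhm_pm, resolution = cfg$resolution,
         n_grid = cfg$n_grid, threshold = cfg$threshold,
         normalization_scope = cfg$normalization_scope, seed = cfg$seed),
    auto_unbox = TRUE, null = "null")
}
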
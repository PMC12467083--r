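#' Interpolate per-point stiffness values into a 2D map
#'
#' Reconstructs the stiffness field over the scanned region from the scattered
#' press points: piecewise-linear (barycentric) interpolation on the Delaunay
#' triangulation of the points inside their convex hull, and nearest-neighbour
#' extrapolation outside it. The linear interpolant is exact at the data
#' points and obeys the maximum principle, so interpolated values never
#' overshoot the input extremes and the session's [0, 1] normalization
#' survives mapping.
#'
#' @param records a normalized `stiffness_records` data frame (columns
#'   `x_rel`, `y_rel`, `s_norm`); at least 3 non-collinear points for 2D
#'   interpolation. With 1 or 2 points the map falls back to
#'   nearest-neighbour values.
#' @param resolution output grid spacing in the units of the coordinates
#'   (mm), or `NULL` to use `n_grid` cells per axis.
#' @param n_grid number of output grid nodes per axis when `resolution` is
#'   `NULL` (default 50).
#' @param roi optional `c(xmin, xmax, ymin, ymax)` for the output extent;
#'   defaults to the bounding box of the points.
#' @param value column of `records` to map (default `"s_norm"`).
#' @return An object of class `stiffness_map`: `grid_x`, `grid_y`, a
#'   `values` matrix indexed `[ix, iy]`, and the source `points`.
#' @examples
#' r <- stiffness_records(1:4, c(0, 10, 0, 10), c(0, 0, 10, 10),
#'                        list(c(1, 1, 1, 1), c(2, 2, 2, 2),
#'                             c(8, 8, 8, 8), c(4, 4, 4, 4)))
#' m <- interpolate_map(normalize_session(r), n_grid = 21)
#' range(m$values)
#' @export
interpolate_map <- function(records, resolution = NULL, n_grid = 50,
                            roi = NULL, value = "s_norm") {
  pts <- check_map_points(records, value)
  if (is.null(roi)) {
    roi <- c(range(pts$x), range(pts$y))
    if (roi[1] == roi[2]) roi[1:2] <- roi[1:2] + c(-0.5, 0.5)
    if (roi[3] == roi[4]) roi[3:4] <- roi[3:4] + c(-0.5, 0.5)
  }
  if (!is.null(resolution)) {
    if (resolution <= 0) stop("`resolution` must be positive")
    grid_x <- seq(roi[1], roi[2], by = resolution)
    grid_y <- seq(roi[3], roi[4], by = resolution)
  } else {
    grid_x <- seq(roi[1], roi[2], length.out = n_grid)
    grid_y <- seq(roi[3], roi[4], length.out = n_grid)
  }

  if (pts$nrow < 3L || pts$collinear) {
    if (pts$nrow >= 3L && pts$collinear) {
      stop("press points are collinear: 2D contouring refused; interpolate along the scan line instead")
    }
    gx <- rep(grid_x, times = length(grid_y))
    gy <- rep(grid_y, each = length(grid_x))
    vals <- matrix(nearest_value(pts, gx, gy),
                   nrow = length(grid_x), ncol = length(grid_y))
  } else {
    ip <- interp::interp(x = pts$x, y = pts$y, z = pts$z,
                         xo = grid_x, yo = grid_y,
                         method = "linear", extrap = FALSE,
                         duplicate = "error", output = "grid")
    vals <- ip$z
    na <- which(is.na(vals))
    if (length(na)) {
      ij <- arrayInd(na, dim(vals))
      vals[na] <- nearest_value(pts, grid_x[ij[, 1]], grid_y[ij[, 2]])
    }
  }
  structure(
    list(grid_x = grid_x, grid_y = grid_y, values = vals,
         points = records),
    class = "stiffness_map"
  )
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("<stiffness_map> %d x %d grid over x [%g, %g], y [%g, %g]; values in [%.4g, %.4g]\n",
              length(x$grid_x), length(x$grid_y),
              min(x$grid_x), max(x$grid_x), min(x$grid_y), max(x$grid_y),
              min(x$values), max(x$values)))
  invisible(x)
}

# shared validation for the interpolation entry points
check_map_points <- function(records, value = "s_norm") {
  if (!is.data.frame(records) ||
      is.null(records$x_rel) || is.null(records$y_rel) ||
      is.null(records[[value]])) {
    stop(sprintf("`records` must be a data frame with x_rel, y_rel and %s columns",
                 value))
  }
  if (!nrow(records)) stop("at least one record is required")
  z <- records[[value]]
  if (any(!is.finite(z))) {
    stop(sprintf("non-finite %s values; run normalize_session() first", value))
  }
  key <- paste(records$x_rel, records$y_rel)
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      vals <- z[key == k]
      if (diff(range(vals)) > 1e-12) {
        ids <- records$point_id[key == k]
        stop(sprintf("points %s share coordinates (%s) with conflicting values",
                     paste(ids, collapse = ", "), k))
      }
    }
    records <- records[!dup, , drop = FALSE]
    z <- records[[value]]
  }
  x <- records$x_rel
  y <- records$y_rel
  collinear <- FALSE
  if (nrow(records) >= 3L) {
    # cross products against the widest lever arm from the centroid:
    # all (near) zero means the cloud has rank < 2, i.e. one line
    cx <- x - mean(x)
    cy <- y - mean(y)
    i0 <- which.max(cx^2 + cy^2)
    cross <- abs(cx[i0] * cy - cy[i0] * cx)
    scale <- max(abs(c(cx, cy)), 1e-12)
    collinear <- all(cross <= 1e-10 * scale^2)
  }
  list(x = x, y = y, z = z, collinear = collinear,
       nrow = nrow(records), records = records)
}

# nearest-data-point value at query locations
nearest_value <- function(pts, qx, qy) {
  vapply(seq_along(qx), function(i) {
    pts$z[which.min((pts$x - qx[i])^2 + (pts$y - qy[i])^2)]
  }, numeric(1))
}

#' Evaluate the stiffness interpolant at arbitrary locations
#'
#' Same interpolant as [interpolate_map()] (piecewise linear inside the convex
#' hull, nearest neighbour outside), evaluated at scattered query points
#' rather than on a grid. At the press points themselves the interpolant
#' reproduces the input values exactly.
#'
#' @inheritParams interpolate_map
#' @param x,y query coordinates.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_at <- function(records, x, y, value = "s_norm") {
  pts <- check_map_points(records, value)
  stopifnot(length(x) == length(y))
  if (pts$nrow < 3L || pts$collinear) {
    if (pts$nrow >= 3L && pts$collinear) {
      stop("press points are collinear: 2D contouring refused; interpolate along the scan line instead")
    }
    return(nearest_value(pts, x, y))
  }
  ip <- interp::interp(x = pts$x, y = pts$y, z = pts$z,
                       xo = x, yo = y, method = "linear",
                       extrap = FALSE, duplicate = "error",
                       output = "points")
  out <- ip$z
  na <- which(is.na(out))
  if (length(na)) out[na] <- nearest_value(pts, x[na], y[na])
  out
}

#' Detect stiff regions in a map
#'
#' Thresholds the map at a fraction of its maximum and reports the connected
#' components of the resulting hot cells (4-neighbour connectivity on the
#' output grid): centroid, bounding box and area fraction of each region.
#' This localizes hard inclusions (a blade or needle under the parenchyma)
#' as the contiguous red zone of the heat map.
#'
#' @param map a [interpolate_map()] result.
#' @param threshold fraction of the map maximum (default 0.5); cells with
#'   `value >= threshold * max` are hot.
#' @return A data frame with one row per region: `region_id`, `centroid_x`,
#'   `centroid_y`, `xmin`, `xmax`, `ymin`, `ymax`, `n_cells`,
#'   `area_fraction`, `max_value`; zero rows if no cell passes the threshold.
#' @export
detect_stiff_region <- function(map, threshold = 0.5) {
  stopifnot(inherits(map, "stiffness_map"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("`threshold` must be a single non-negative number")
  }
  v <- map$values
  cutoff <- threshold * max(v)
  # small absolute slack so barycentric rounding cannot drop boundary cells
  hot <- which(v >= cutoff - 1e-12 * max(abs(cutoff), 1))
  empty <- data.frame(region_id = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), xmin = numeric(0),
                      xmax = numeric(0), ymin = numeric(0), ymax = numeric(0),
                      n_cells = integer(0), area_fraction = numeric(0),
                      max_value = numeric(0))
  if (!length(hot)) return(empty)

  nx <- nrow(v)
  ij <- arrayInd(hot, dim(v))
  idx <- seq_along(hot)                     # vertex ids in the lattice graph
  pos <- integer(length(v))
  pos[hot] <- idx
  edges <- integer(0)
  for (k in idx) {
    i <- ij[k, 1]; j <- ij[k, 2]
    # right and up neighbours are enough for an undirected graph
    if (i < nx) {
      nb <- hot[k] + 1L
      if (pos[nb] > 0L) edges <- c(edges, k, pos[nb])
    }
    nb <- hot[k] + nx
    if (nb <= length(v) && pos[nb] > 0L) edges <- c(edges, k, pos[nb])
  }
  g <- igraph::make_empty_graph(n = length(hot), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership

  gx <- map$grid_x[ij[, 1]]
  gy <- map$grid_y[ij[, 2]]
  vv <- v[hot]
  out <- do.call(rbind, lapply(sort(unique(comp)), function(cid) {
    m <- comp == cid
    data.frame(region_id = cid,
               centroid_x = mean(gx[m]), centroid_y = mean(gy[m]),
               xmin = min(gx[m]), xmax = max(gx[m]),
               ymin = min(gy[m]), ymax = max(gy[m]),
               n_cells = sum(m),
               area_fraction = sum(m) / length(v),
               max_value = max(vv[m]))
  }))
  rownames(out) <- NULL
  out
}

#' Render a stiffness map to files
#'
#' Writes the interpolated value matrix as CSV (first column `x`, one column
#' per `y` grid node) and, alongside it, a rasterized heat-map PNG using the
#' conventional palette — red for stiff, blue/green for soft.
#'
#' @param map a [interpolate_map()] result.
#' @param path_prefix output path prefix; `<prefix>_values.csv` and
#'   `<prefix>.png` are written.
#' @return Named character vector with the written file paths, invisibly.
#' @export
render_map <- function(map, path_prefix) {
  stopifnot(inherits(map, "stiffness_map"))
  if (!length(map$values)) stop("cannot render an empty map")
  dir <- dirname(path_prefix)
  if (!dir.exists(dir)) stop(sprintf("output directory does not exist: %s", dir))

  csv_path <- paste0(path_prefix, "_values.csv")
  df <- data.frame(x = map$grid_x, map$values, check.names = FALSE)
  names(df) <- c("x", sprintf("y=%.9g", map$grid_y))
  utils::write.csv(df, csv_path, row.names = FALSE)

  png_path <- paste0(path_prefix, ".png")
  pal <- grDevices::colorRampPalette(
    c("#2c2c9e", "#00a0c8", "#27ad27", "#e8e84a", "#e87b1e", "#cc2222"))(256)
  grDevices::png(png_path, width = 720, height = 640)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::image(map$grid_x, map$grid_y, map$values, col = pal,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = "Relative stiffness", useRaster = TRUE)
  graphics::points(map$points$x_rel, map$points$y_rel, pch = 3, col = "black")

  invisible(c(values_csv = csv_path, png = png_path))
}

#' Read back a rendered map value matrix
#'
#' @param path a `<prefix>_values.csv` file written by [render_map()].
#' @return A list with `grid_x`, `grid_y` and the `values` matrix.
#' @export
read_map_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  grid_x <- df[[1]]
  grid_y <- as.numeric(sub("^y=", "", names(df)[-1]))
  values <- as.matrix(df[, -1, drop = FALSE])
  dimnames(values) <- NULL
  list(grid_x = grid_x, grid_y = grid_y, values = values)
}
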
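test_that("a constant stiffness field interpolates to a constant map", {
  r <- grid_records(c(0, 10, 20), c(0, 10, 20), rep(0.4, 9))
  m <- interpolate_map(r, n_grid = 15)
  expect_true(all(abs(m$values - 0.4) < 1e-12))
  expect_equal(dim(m$values), c(15, 15))
})

test_that("the interpolant is exact at press points and bounded by the input extremes", {
  set.seed(61)
  for (k in 1:10) {
    n <- sample(5:20, 1)
    x <- runif(n, 0, 40)
    y <- runif(n, 0, 40)
    v <- runif(n)
    rec <- stiffness_records(seq_len(n), x, y,
                             lapply(v, function(z) c(z, 0, 0, 0)))
    rec$s_norm <- v
    # exactness at the data points
    expect_lt(max(abs(interpolate_at(rec, x, y) - v)), 1e-12)
    # maximum principle on the gridded map
    m <- interpolate_map(rec, n_grid = 25)
    expect_gte(min(m$values), min(v) - 1e-12)
    expect_lte(max(m$values), max(v) + 1e-12)
  }
})

test_that("a single hot point dominates the map argmax at its own coordinates", {
  xs <- c(0, 10, 20, 30)
  vals <- rep(0, 16); vals[10] <- 1      # point (x = 10, y = 20) in row-major
  r <- grid_records(xs, xs, vals)
  hot <- r[r$s_norm == 1, ]
  m <- interpolate_map(r, n_grid = 41)
  ij <- arrayInd(which.max(m$values), dim(m$values))
  dx <- diff(m$grid_x)[1]
  expect_lt(abs(m$grid_x[ij[1]] - hot$x_rel), dx + 1e-9)
  expect_lt(abs(m$grid_y[ij[2]] - hot$y_rel), dx + 1e-9)
})

test_that("degenerate geometries are refused or fall back as documented", {
  # collinear points: 2D contouring refused with an explicit message
  rec <- stiffness_records(1:4, 1:4, 2 * (1:4),
                           lapply(1:4, function(i) c(i, 0, 0, 0)))
  rec$s_norm <- c(0, 0.2, 0.4, 1)
  expect_error(interpolate_map(rec), "collinear")

  # duplicate coordinates with conflicting values: refused, points named
  rec2 <- stiffness_records(1:4, c(0, 0, 10, 10), c(0, 0, 0, 10),
                            lapply(1:4, function(i) c(i, 0, 0, 0)))
  rec2$s_norm <- c(0.1, 0.9, 0.5, 0.7)
  expect_error(interpolate_map(rec2), "points 1, 2.*conflicting")

  # one or two points: nearest-neighbour fallback
  rec3 <- stiffness_records(1:2, c(0, 10), c(0, 0),
                            list(c(1, 0, 0, 0), c(3, 0, 0, 0)))
  rec3$s_norm <- c(0, 1)
  m <- interpolate_map(rec3, n_grid = 11)
  expect_setequal(unique(as.vector(m$values)), c(0, 1))
})

test_that("stiff-region detection reports centroids, components and forced cases", {
  xs <- c(0, 10, 20, 30)
  vals <- rep(0, 16); vals[10] <- 1
  r <- grid_records(xs, xs, vals)
  m <- interpolate_map(r, n_grid = 41)
  reg <- detect_stiff_region(m, 0.5)
  expect_equal(nrow(reg), 1)
  dx <- diff(m$grid_x)[1]
  expect_lt(abs(reg$centroid_x - 10), 2 * dx)
  expect_lt(abs(reg$centroid_y - 20), 2 * dx)

  # constant map: whole grid at threshold <= 1, empty above the maximum
  rc <- grid_records(xs, xs, rep(0.5, 16))
  mc <- interpolate_map(rc, n_grid = 21)
  whole <- detect_stiff_region(mc, 1)
  expect_equal(whole$n_cells, 21 * 21)
  expect_equal(whole$area_fraction, 1)
  expect_equal(nrow(detect_stiff_region(mc, 1.5)), 0)

  # two disjoint hot spots: two connected components
  vals2 <- rep(0, 16); vals2[1] <- 1; vals2[16] <- 1
  r2 <- grid_records(xs, xs, vals2)
  m2 <- interpolate_map(r2, n_grid = 41)
  reg2 <- detect_stiff_region(m2, 0.6)
  expect_equal(nrow(reg2), 2)
  expect_equal(sort(round(reg2$centroid_x)), c(0, 30), tolerance = 2)
})

test_that("rendered maps round-trip through the matrix CSV and place the maximum correctly", {
  xs <- c(0, 10, 20, 30)
  vals <- rep(0.1, 16); vals[7] <- 1    # x = 20, y = 10
  r <- grid_records(xs, xs, vals)
  m <- interpolate_map(r, n_grid = 31)
  dir <- withr::local_tempdir()
  paths <- render_map(m, file.path(dir, "scan"))
  expect_true(file.exists(paths[["values_csv"]]))
  expect_true(file.exists(paths[["png"]]))

  back <- read_map_matrix(paths[["values_csv"]])
  expect_equal(back$values, m$values, tolerance = 1e-9)
  expect_equal(back$grid_x, m$grid_x, tolerance = 1e-9)
  ij <- arrayInd(which.max(back$values), dim(back$values))
  expect_lt(abs(back$grid_x[ij[1]] - 20), diff(m$grid_x)[1] + 1e-9)
  expect_lt(abs(back$grid_y[ij[2]] - 10), diff(m$grid_y)[1] + 1e-9)

  expect_error(render_map(m, file.path(dir, "nope", "scan")),
               "does not exist")
})
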
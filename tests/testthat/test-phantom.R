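test_that("local stiffness takes the forced values on, near and away from the inclusion", {
  ph <- blade_phantom(multiplier = 30, depth_attenuation = 0.8)
  # on the blade axis: background x multiplier x attenuation
  expect_equal(local_stiffness(ph, 20, 20), 1 * 30 * 0.8)
  # far from the blade: exactly background
  expect_equal(local_stiffness(ph, 20, 5), 1)
  # continuous taper: strictly between peak and background at the edge zone
  mid <- local_stiffness(ph, 20, 20 + 3)   # half-width 2 + taper 2
  expect_gt(mid, 1)
  expect_lt(mid, 24)

  uniform <- phantom_field()
  expect_equal(local_stiffness(uniform, c(1, 20, 39), c(1, 20, 39)),
               rep(1, 3))

  expect_error(local_stiffness(ph, 41, 20), "outside the phantom roi")
  expect_error(phantom_field(inclusion = list(x0 = -5, y0 = 20, x1 = 30, y1 = 20,
                                              half_width_mm = 2, multiplier = 30,
                                              depth_attenuation = 1)),
               "inside the roi")
})

test_that("a zero-depth press leaves the spectrum unchanged and shifts scale linearly with depth", {
  ph <- blade_phantom()
  ch <- fast_channels()
  grid <- fast_grid()
  p0 <- palpation_protocol(cbind(20, 20), press_depth_mm = 0, seed = 1)
  pr <- simulate_press(ph, p0, ch, grid, quiet_noise(), 20, 20)
  expect_identical(pr$contact$intensity, pr$pressed$intensity)
  expect_equal(pr$true_shifts_pm, rep(0, 4))

  p1 <- palpation_protocol(cbind(20, 20), press_depth_mm = 1, seed = 1)
  p2 <- palpation_protocol(cbind(20, 20), press_depth_mm = 2, seed = 1)
  s1 <- simulate_press(ph, p1, ch, grid, quiet_noise(), 20, 5)$true_shifts_pm
  s2 <- simulate_press(ph, p2, ch, grid, quiet_noise(), 20, 5)$true_shifts_pm
  expect_equal(s2, 2 * s1)
})

test_that("direct contact over the inclusion reads an order of magnitude above side contact", {
  ph <- blade_phantom(multiplier = 30, depth_attenuation = 1)
  ch <- fast_channels()
  grid <- fast_grid()
  proto <- palpation_protocol(cbind(20, 20), press_depth_mm = 2,
                              side_contact_attenuation = 0.1,
                              influence_radius_mm = 8, seed = 1)
  direct <- simulate_press(ph, proto, ch, grid, quiet_noise(), 20, 20)
  side <- simulate_press(ph, proto, ch, grid, quiet_noise(), 20, 28)  # at the influence edge
  S_direct <- sum(abs(direct$true_shifts_pm))
  S_side <- sum(abs(side$true_shifts_pm))
  expect_equal(S_direct / S_side, 10, tolerance = 1e-12)
  expect_equal(direct$mode, "direct")
  expect_equal(side$mode, "side")

  # side contact splits the pair along the offset axis into red/blue shifts
  expect_true(any(side$true_shifts_pm > 0) && any(side$true_shifts_pm < 0))
  # centered contact loads all channels with the same sign
  expect_true(all(direct$true_shifts_pm > 0))
})

test_that("points on the inclusion always out-shift background points when the object is stiffer", {
  ch <- fast_channels()
  grid <- fast_grid()
  for (mult in c(2, 10, 30)) {
    ph <- blade_phantom(multiplier = mult)
    proto <- palpation_protocol(cbind(20, 20), seed = 1)
    on_axis <- simulate_press(ph, proto, ch, grid, quiet_noise(), 20, 20)
    off <- simulate_press(ph, proto, ch, grid, quiet_noise(), 8, 4)
    expect_gt(sum(abs(on_axis$true_shifts_pm)), sum(abs(off$true_shifts_pm)))
  }
})

test_that("session mean summed shift increases strictly with press depth on a uniform field", {
  ph <- phantom_field()
  ch <- fast_channels()
  grid <- fast_grid()
  pts <- lattice_points(ph, n = 2)
  mean_S <- vapply(c(0.5, 1, 2, 3), function(depth) {
    proto <- palpation_protocol(pts, press_depth_mm = depth, seed = 1)
    ses <- simulate_session(ph, proto, ch, grid, quiet_noise())
    mean(ses$points$true_S_pm)
  }, numeric(1))
  expect_true(all(diff(mean_S) > 0))
})

test_that("simulated sessions are byte-identical under a fixed seed and write a usable manifest", {
  ph <- blade_phantom()
  ch <- fast_channels()
  grid <- fast_grid()
  proto <- palpation_protocol(lattice_points(ph, n = 2), seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_session(ph, proto, ch, grid, noise_model(0.01), dir = d1)
  s2 <- simulate_session(ph, proto, ch, grid, noise_model(0.01), dir = d2)

  for (f in c("point01_contact.csv", "point03_pressed.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  m <- read_manifest(file.path(d1, "manifest.json"))
  expect_equal(nrow(m$points), 4)
  expect_equal(m$roi, c(40, 40))
  sp <- read_spectrum(file.path(d1, m$points$contact[1]))
  expect_s3_class(sp, "fbg_spectrum")
})
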
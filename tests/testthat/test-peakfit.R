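test_that("windows split at midpoints between nominal centers and translate with them", {
  ch <- bragg_channels(c(1520, 1540, 1560, 1580))
  sp <- synth_spectrum(ch, grid = wavelength_grid(1510, 2, 40001L),
                       noise = quiet_noise())
  win <- partition_windows(sp, ch)
  expect_equal(win$lo_nm, c(1510, 1530, 1550, 1570))
  expect_equal(win$hi_nm, c(1530, 1550, 1570, 1590))

  ch2 <- bragg_channels(c(1521, 1541, 1561, 1581))
  win2 <- partition_windows(sp, ch2)
  expect_equal(win2$lo_nm[-1], win$lo_nm[-1] + 1)
  expect_equal(win2$hi_nm[-4], win$hi_nm[-4] + 1)

  expect_error(partition_windows(sp, bragg_channels(c(1500, 1540, 1560, 1580))),
               "inside the grid span")
})

test_that("noiseless off-grid centers are recovered to better than 0.01 pm and match the oracle", {
  ch <- one_channel(1540)
  grid <- narrow_grid(1540)
  win <- list(channel_id = 1L, lo_nm = 1539, hi_nm = 1541)
  set.seed(101)
  for (k in 1:20) {
    true <- 1540 + runif(1, -1, 1) * 0.001          # off-grid by up to 1 pm
    sp <- synth_spectrum(ch, true, grid, envelope = flat_envelope(),
                         noise = quiet_noise(), baseline = 0)
    fit <- fit_gaussian_peak(sp, win)
    expect_true(fit$converged)
    expect_lt(abs(fit$center_nm - true) * 1e3, 0.01)
    expect_lt(abs(fit$center_nm - oracle_center(true, 60, grid)) * 1e3, 0.01)
  }
})

test_that("degenerate windows are flagged instead of returning silent garbage", {
  grid <- narrow_grid(1540)
  flat <- fbg_spectrum(grid, rep(0, grid$n_points))
  fit <- fit_gaussian_peak(flat, list(channel_id = 1L, lo_nm = 1539, hi_nm = 1541))
  expect_false(fit$converged)
  expect_match(fit$message, "flat or all-zero")

  expect_error(
    fit_gaussian_peak(synth_spectrum(one_channel(), grid = grid,
                                     noise = quiet_noise()),
                      list(channel_id = 1L, lo_nm = 1540, hi_nm = 1540.01)),
    "at least 8"
  )
})

test_that("the fitted center is invariant to uniform intensity scaling", {
  ch <- one_channel(1540)
  grid <- narrow_grid(1540)
  win <- list(channel_id = 1L, lo_nm = 1539, hi_nm = 1541)
  sp <- synth_spectrum(ch, 1540.0007, grid, envelope = flat_envelope(),
                       noise = noise_model(0.01, seed = 5))
  f1 <- fit_gaussian_peak(sp, win)
  sp10 <- fbg_spectrum(grid, sp$intensity * 10)
  f10 <- fit_gaussian_peak(sp10, win)
  expect_lt(abs(f1$center_nm - f10$center_nm) * 1e3, 0.001)
  expect_equal(f10$amplitude / f1$amplitude, 10, tolerance = 1e-6)
})

test_that("extract_peaks fits all four channels and isolates per-channel failures", {
  ch <- fast_channels()
  grid <- fast_grid()
  sp <- synth_spectrum(ch, grid = grid, noise = quiet_noise())
  fits <- extract_peaks(sp, ch)
  expect_length(fits, 4)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  err_pm <- abs(vapply(fits, `[[`, numeric(1), "center_nm") -
                ch$nominal_center_nm) * 1e3
  expect_true(all(err_pm < 0.05))

  # remove one peak: its channel is flagged, the others still converge
  sp3 <- synth_spectrum(ch[-2, ], ch$nominal_center_nm[-2], grid,
                        noise = quiet_noise(), baseline = 0)
  fits3 <- extract_peaks(sp3, ch)
  conv <- vapply(fits3, `[[`, logical(1), "converged")
  expect_equal(conv, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("center accuracy does not degrade with amplitude rank under the ramp envelope", {
  ch <- fast_channels()
  grid <- fast_grid()
  set.seed(11)
  offs <- runif(4, -1, 1) * 0.001
  sp <- synth_spectrum(ch, ch$nominal_center_nm + offs, grid,
                       noise = quiet_noise())
  fits <- extract_peaks(sp, ch)
  err_pm <- abs(vapply(fits, `[[`, numeric(1), "center_nm") -
                (ch$nominal_center_nm + offs)) * 1e3
  # noiseless: every channel is recovered essentially exactly regardless of
  # its envelope-scaled amplitude
  expect_true(all(err_pm < 0.01))
})

test_that("shift computation is signed, antisymmetric and refuses unconverged channels", {
  ch <- fast_channels()
  grid <- fast_grid()
  ref <- extract_peaks(synth_spectrum(ch, grid = grid, noise = quiet_noise()), ch)

  expect_equal(unclass(compute_shifts(ref, ref)),
               c(d1 = 0, d2 = 0, d3 = 0, d4 = 0))

  # +50 pm on channel 2, -30 pm on channel 4 (blue-shift)
  moved <- ch$nominal_center_nm + c(0, 0.05, 0, -0.03)
  prs <- extract_peaks(synth_spectrum(ch, moved, grid, noise = quiet_noise()), ch)
  d <- compute_shifts(ref, prs)
  expect_equal(unclass(d), c(d1 = 0, d2 = 50, d3 = 0, d4 = -30),
               tolerance = 1e-6)
  expect_equal(unclass(compute_shifts(prs, ref)), -unclass(d),
               tolerance = 1e-12)

  broken <- ref
  broken[[3]]$converged <- FALSE
  expect_error(compute_shifts(ref, broken), "refused.*channel 3")
})
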
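test_that("sinusoidal waveform matches the closed form", {
  bc <- generate_curve(curve_spec("sin", Ap2p = 10, rate = 12, duration = 60))
  expect_equal(bc$amp, 5 * sin(2 * pi * bc$t / 5), tolerance = 1e-12)
  expect_false(any(bc$xray_on))
  # on a grid that hits the extrema (Tcycle/4 a grid multiple), the inhale
  # maximum at Tcycle/4 = 1.25 s equals Ap2p/2 and max - min equals Ap2p
  fine <- generate_curve(curve_spec("sin", 10, 12, 60, grid_dt = 0.025))
  expect_equal(fine$amp[fine$t == 1.25], 5.0, tolerance = 1e-12)
  expect_equal(diff(range(fine$amp)), 10, tolerance = 1e-9)
})

test_that("cos^6 waveform is non-negative with maxima Ap2p/2 at cycle marks", {
  bc <- generate_curve(curve_spec("cos6", Ap2p = 10, rate = 12, duration = 60))
  expect_equal(bc$amp[bc$t == 0], 5.0, tolerance = 1e-12)
  expect_true(all(bc$amp >= 0))
  marks <- bc$t %in% seq(0, 60, by = 5)
  expect_equal(bc$amp[marks], rep(5, sum(marks)), tolerance = 1e-9)
})

test_that("design-space edges are accepted and bounds enforced", {
  expect_silent(spec <- curve_spec("sin", Ap2p = 2, rate = 6, duration = 60))
  bc <- generate_curve(spec)
  expect_equal(min(bc$amp), -1.0, tolerance = 1e-12)
  expect_warning(curve_spec("sin", Ap2p = 1, rate = 12, duration = 60),
                 "design space")
  expect_warning(curve_spec("sin", Ap2p = 10, rate = 25, duration = 60),
                 "design space")
  expect_error(curve_spec("sin", Ap2p = 10, rate = 12, duration = 10),
               "3 cycle")
  expect_error(curve_spec("sin", Ap2p = 10, rate = 12, duration = 60,
                          grid_dt = 0), "positive")
})

test_that("jittered curves are reproducible, seed-sensitive and jump-free", {
  mk <- function(seed) generate_curve(
    curve_spec("cos6", 10, 12, 120, amp_jitter = 0.15, rate_jitter = 0.1,
               seed = seed))
  a <- mk(7); b <- mk(7); c <- mk(8)
  expect_identical(a$amp, b$amp)
  expect_false(identical(a$amp, c$amp))
  # phase continuity + smooth amplitude envelope: sample-to-sample jumps stay
  # bounded by a modest multiple of the jitter-free maximum slope
  ref <- generate_curve(curve_spec("cos6", 10, 12, 120))
  expect_lt(max(abs(diff(a$amp))), 3 * max(abs(diff(ref$amp))))
  # amplitude factors are truncated at 3 sigma
  expect_lt(max(a$amp), 5 * (1 + 3 * 0.15) + 1e-6)
})

test_that("table profile is a staircase with the fixed increment", {
  tp <- generate_table_profile(3, dwell = 8, move_duration = 1)
  expect_equal(max(tp$displacement), 3 * 34.5, tolerance = 1e-9)
  expect_true(all(diff(tp$displacement) >= -1e-12))
  # plateau levels differ by exactly one step
  plateaus <- unique(round(tp$displacement[
    vapply(tp$t, function(x) all(abs(x - tp$move_onsets) > 1.5), logical(1))], 6))
  expect_equal(diff(sort(plateaus)), rep(34.5, 3), tolerance = 1e-6)
  tp5 <- generate_table_profile(5, dwell = 8, move_duration = 1)
  expect_gte(max(tp5$t), 5 * (8 + 1))
  tp1 <- generate_table_profile(1, dwell = 4)
  expect_equal(length(tp1$move_onsets), 1L)
  expect_error(generate_table_profile(3, dwell = 8, step_size = 0), "positive")
})

test_that("identity emulation is a no-op and noise is seed-deterministic", {
  truth <- sine_curve()
  out <- emulate_surrogate(truth)
  expect_identical(out$amp, truth$amp)
  n1 <- emulate_surrogate(truth, espec = surrogate_spec(noise_sd = 0.1, seed = 1))
  n2 <- emulate_surrogate(truth, espec = surrogate_spec(noise_sd = 0.1, seed = 1))
  n3 <- emulate_surrogate(truth, espec = surrogate_spec(noise_sd = 0.1, seed = 2))
  expect_identical(n1$amp, n2$amp)
  expect_false(identical(n1$amp, n3$amp))
})

test_that("emulated latency is recovered by the cross-correlation oracle", {
  truth <- sine_curve(duration = 100)
  lagged <- emulate_surrogate(truth, espec = surrogate_spec(latency = 0.045))
  lag <- oracle_xcorr_lag(truth$amp, lagged$amp, 0.02, max_lag_s = 0.5)
  expect_equal(lag, 0.045, tolerance = 0.002)
})

test_that("an injected spike creates exactly one dominant excursion", {
  st <- simulate_surface_study(Ap2p = 10, rate = 12, n_steps = 1,
                               espec = surrogate_spec(artifact_heights = 12,
                                                      contamination_gain = 0))
  out <- st$emulated
  iv <- st$events$intervals
  gap <- out$t >= iv[1, 2] & out$t < iv[2, 1]
  # inside the step window the curve exceeds the truth's global max by >= h/2
  expect_gte(max(out$amp[gap]), max(st$truth$amp) + 6)
  # and nowhere else
  expect_lte(max(out$amp[!gap]), max(st$truth$amp) + 1e-9)
})

test_that("rendered spheres reproduce analytic centre-of-mass positions", {
  geom <- phantom_geometry()
  ps <- render_phantom_series(0, geom)
  expect_equal(com_is(ps$volumes[[1]], geom), 0, tolerance = 0.05)
  ps2 <- render_phantom_series(c(0, 5), geom)
  coms <- vapply(ps2$volumes, com_is, numeric(1), geometry = geom)
  expect_equal(diff(coms), 5, tolerance = 0.2)
  # fractional offsets: COM error bounded by half a voxel
  offs <- c(-7.3, -2.5, 0.4, 3.7, 9.1)
  ps3 <- render_phantom_series(offs, geom)
  coms3 <- vapply(ps3$volumes, com_is, numeric(1), geometry = geom)
  expect_lt(max(abs(coms3 - offs)), geom$voxel_size / 2)
  # HU construction separates tumor from background across the threshold
  v <- ps$volumes[[1]]
  expect_true(all(v[v > -800] > -200) && all(v[v < 50] < -200))
  expect_error(render_phantom_series(30, geom), "clipped")
})

test_that("phantom series round-trips through NIfTI with a JSON sidecar", {
  dir <- withr::local_tempdir()
  geom <- phantom_geometry(grid_n = 24, tumor_radius = 5)
  ps <- render_phantom_series(c(-2, 2), geom, bin_labels = c("a", "b"))
  sidecar <- write_phantom_series(ps, dir)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  expect_equal(meta$true_positions_mm, c(-2, 2))
  vol <- RNifti::readNifti(file.path(dir, meta$files[1]))
  expect_equal(as.numeric(max(vol)), geom$tumor_hu)
  expect_equal(dim(vol), rep(24L, 3))
})

test_that("curve specs round-trip through YAML and JSON", {
  spec <- curve_spec("cos6", 8, 15, 45, amp_jitter = 0.1, seed = 3)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_curve_spec(spec, path)
    back <- read_curve_spec(path)
    expect_equal(back[names(back) != "Tcycle"],
                 spec[names(spec) != "Tcycle"], ignore_attr = TRUE)
  }
})
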
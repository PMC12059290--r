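test_that("injected spikes are detected at their onsets with the right scale", {
  st <- simulate_surface_study(Ap2p = 10, rate = 12, n_steps = 3, seed = 2)
  arts <- detect_artifacts(st$emulated, st$events)
  expect_length(arts, 3)
  onsets <- vapply(arts, function(a) a$onset, numeric(1))
  expect_lt(max(abs(onsets - st$profile$move_onsets)), 0.04)
  # auto heights encode the contamination gain exactly
  scales <- vapply(arts, function(a) a$scale_factor, numeric(1))
  expect_equal(scales, rep(st$espec$contamination_gain, 3), tolerance = 1e-9)
  expect_equal(vapply(arts, function(a) a$xray_segment_index, integer(1)), 1:3)
})

test_that("clean curves produce no artifacts", {
  st <- simulate_surface_study(n_steps = 2,
                               espec = surrogate_spec())  # identity chain
  expect_length(detect_artifacts(st$emulated, st$events), 0)
})

test_that("the scaling factor is artifact height over the preceding maximum", {
  # spike of 12 mm after cycles whose max-above-baseline is 6 mm -> scale 2
  st <- simulate_surface_study(Ap2p = 12, rate = 12, n_steps = 1,
                               espec = surrogate_spec(artifact_heights = 12,
                                                      contamination_gain = 0))
  arts <- detect_artifacts(st$emulated, st$events)
  expect_length(arts, 1)
  expect_equal(arts[[1]]$height, 12, tolerance = 1e-6)
  expect_equal(arts[[1]]$preceding_max, 6, tolerance = 0.01)
  expect_equal(arts[[1]]$scale_factor, 2, tolerance = 0.01)
})

test_that("stripping excises spikes and leaves the baseline continuous", {
  st <- simulate_surface_study(Ap2p = 10, rate = 12, n_steps = 2,
                               espec = surrogate_spec(artifact_heights = c(15, 15),
                                                      contamination_gain = 0))
  arts <- detect_artifacts(st$emulated, st$events)
  expect_length(arts, 2)
  stripped <- strip_system_correction(st$emulated, arts)
  # without contamination the stripped curve equals the truth away from the
  # bridged windows, and no residual step remains between segments
  in_window <- rep(FALSE, length(stripped$t))
  for (a in arts)
    in_window <- in_window | (stripped$t >= a$window[1] & stripped$t <= a$window[2])
  expect_lt(max(abs(stripped$amp[!in_window] - st$truth$amp[!in_window])), 1e-9)
  expect_lt(max(abs(stripped$amp[in_window] - st$truth$amp[in_window])), 0.2)
  # no artifacts -> identity
  expect_identical(strip_system_correction(st$truth, list()), st$truth)
})

test_that("the full correction inverts the emulation model", {
  st <- simulate_surface_study(Ap2p = 10, rate = 12, n_steps = 1,
                               espec = surface_espec(amp_scale = 1))
  res <- correct_surface_curve(st$emulated, st$profile, st$events)
  out <- res$curve
  in_window <- rep(FALSE, length(out$t))
  for (a in res$artifacts)
    in_window <- in_window | (out$t >= a$window[1] & out$t <= a$window[2])
  # scale 1, gain 1: corrected curve equals truth within 2% of Ap2p
  # everywhere outside the artifact windows
  expect_lt(max(abs(out$amp[!in_window] - st$truth$amp[!in_window])), 0.02 * 10)
  # correction never touches samples before the first X-ray-off
  first_off <- st$events$intervals[1, 2]
  pre <- out$t < first_off
  expect_equal(out$amp[pre], st$emulated$amp[pre], tolerance = 1e-12)
})

test_that("correction round trip meets the amplitude and rate bounds", {
  # emulation grid: amplitudes and gains varied, 1-5 couch steps
  cases <- expand.grid(Ap2p = c(2, 10, 20), gain = c(0.5, 1, 2),
                       steps = c(1, 3, 5))
  cases <- cases[cases$steps == 3 | (cases$Ap2p == 10 & cases$gain == 1), ]
  for (i in seq_len(nrow(cases))) {
    st <- simulate_surface_study(
      Ap2p = cases$Ap2p[i], rate = 12, n_steps = cases$steps[i],
      espec = surface_espec(contamination_gain = cases$gain[i]), seed = i)
    res <- correct_surface_curve(st$emulated, st$profile, st$events)
    cm <- compare_maxima(res$curve, st$truth)
    expect_lt(max(abs(cm$per_cycle_pct)), 10)
    br <- br_stats(detect_cycles(res$curve))
    expect_lt(abs(br$mean_bpm - 12) / 12 * 100, 1)
  }
})

test_that("a missing scaling factor for a moved segment is an error", {
  st <- simulate_surface_study(n_steps = 1)
  expect_error(apply_table_correction(st$emulated, st$profile, list(),
                                      st$events),
               "segment 1")
})

test_that("reference-tool subtraction removes couch motion exactly", {
  t <- seq(0, 60, 0.02)
  stair <- 34.5 * pmin(pmax((t - 20) / 1, 0), 1)
  sine <- 5 * sin(2 * pi * t / 5)
  phantom <- breathing_curve(t, sine + stair, system_label = "phantom")
  table <- breathing_curve(t, stair, system_label = "table")
  out <- subtract_reference_tool(phantom, table)
  expect_equal(out$amp, sine, tolerance = 1e-12)
  # zero couch track is the identity; identical tracks cancel
  zero <- breathing_curve(t, rep(0, length(t)))
  expect_equal(subtract_reference_tool(phantom, zero)$amp, phantom$amp)
  expect_equal(subtract_reference_tool(table, table)$amp, rep(0, length(t)))
  # linear and self-inverse under negation
  neg <- table; neg$amp <- -neg$amp
  expect_equal(subtract_reference_tool(phantom, neg)$amp, sine + 2 * stair,
               tolerance = 1e-12)
  short <- breathing_curve(t[1:100], stair[1:100])
  expect_error(subtract_reference_tool(phantom, short), "grid")
})
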
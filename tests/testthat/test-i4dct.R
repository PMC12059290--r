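test_that("training analysis extracts cycle period, rotation time and RBC", {
  bc <- sine_curve(Ap2p = 10, rate = 12, duration = 40)
  tp <- analyze_training(bc, first_on = 20)
  expect_equal(tp$mean_cycle_s, 5.0, tolerance = 1e-3)
  # largest rotation time <= mean_cycle/4 from {0.25, 0.35, 0.5, 1.0}
  expect_equal(tp$rotation_time_s, 1.0)
  fast <- analyze_training(sine_curve(rate = 20, duration = 40), first_on = 20)
  expect_equal(fast$rotation_time_s, 0.5)  # 3 s cycle -> 0.75 bound
  # identical cycles average to any single cycle's phase-resampled form
  rbc <- tp$rbc
  pk <- 21.25  # an inhalation maximum
  single <- approx(bc$t, bc$amp, xout = seq(pk, pk + 5, length.out = 101))$y
  expect_equal(rbc$amp, single, tolerance = 1e-3)
  # RBC conventions: starts at the maximum, minimum strictly inside, periodic
  expect_equal(which.max(abs(rbc$amp - max(rbc$amp)) < 1e-3), 1)
  expect_true(which.min(rbc$amp) > 1 && which.min(rbc$amp) < 101)
  expect_lt(abs(rbc$amp[1] - rbc$amp[101]), 0.05 * diff(range(rbc$amp)))
})

test_that("training windows with fewer than three cycles are rejected", {
  slow <- sine_curve(Ap2p = 10, rate = 6, duration = 40)  # 2 cycles in 20 s
  expect_error(analyze_training(slow, first_on = 20), "3")
  short <- sine_curve(duration = 30)
  expect_error(analyze_training(short, first_on = 10), "before the start")
})

test_that("triggers on a regular curve are valley-locked and equal-length", {
  st <- simulate_i4dct_study(Ap2p = 10, rate = 12, n_segments = 4)
  seg <- attr(st$events, "segments")
  expect_equal(nrow(seg), 4)
  # each on-duration covers one full cycle plus the rotation overhead
  expect_true(all(seg$duration >= 5.0 & seg$duration <= 6.0 + 1e-9))
  expect_lt(max(seg$duration) - min(seg$duration), 0.02)
  # on-edges sit on exhalation valleys of the curve
  cs <- detect_cycles(st$curve)
  for (on in seg$on)
    expect_lt(min(abs(cs$valleys$time - on)), 1e-3)
  # zero segments -> empty events
  empty <- simulate_triggers(st$curve, st$params, 0)
  expect_equal(nrow(empty$intervals), 0)
})

test_that("an anomalous cycle keeps the beam on until a valid cycle ends", {
  periods <- c(2.5, rep(5, 13)); periods[8] <- 2   # short cycle at ~32 s
  bc <- sine_with_periods(periods)
  params <- analyze_training(bc, first_on = 20)
  ev <- simulate_triggers(bc, params, n_segments = 3)
  seg <- attr(ev, "segments")
  hit <- which(seg$cycles > 1)
  expect_length(hit, 1)
  # the affected segment spans at least two cycle lengths
  expect_gte(seg$duration[hit], 2 + 5)
  expect_true(all(seg$duration[-hit] < 7))
})

test_that("trigger comparison statistics follow their definitions", {
  a <- xray_events(c(10, 20, 30), c(16.5, 26.5, 36.4))
  expect_equal(compare_triggers(a, a)$on_diff_mean, 0)
  expect_equal(compare_triggers(a, a)$dur_diff_sd, 0)
  b <- xray_events(c(10, 20, 30) + 0.03, c(16.5, 26.5, 36.4) + 0.03)
  cmp <- compare_triggers(a, b)
  expect_equal(cmp$on_diff_mean, 0.03, tolerance = 1e-9)
  expect_equal(cmp$on_diff_sd, 0, tolerance = 1e-9)
  expect_equal(cmp$dur_diff_mean, 0, tolerance = 1e-9)
  # durations 6.5/6.5/6.4 vs 6.5/6.4/6.4 differ by ~33 ms on average
  c2 <- xray_events(c(10, 20, 30), c(16.5, 26.4, 36.4))
  expect_equal(abs(compare_triggers(a, c2)$dur_diff_mean), 1 / 30,
               tolerance = 1e-9)
  expect_warning(compare_triggers(a, xray_events(10, 16.5)), "prefix")
})

test_that("bin placement matches closed forms on a pure sine", {
  st <- simulate_i4dct_study(Ap2p = 10, rate = 12, n_segments = 3)
  pp <- plan_bins(st$params$rbc, st$curve, st$events, "phase")
  # phase-mode timestamps are uniformly spaced by Tcycle/10 (as a set)
  for (s in 1:3) {
    tt <- sort(pp$timestamps[s, ])
    expect_equal(unname(diff(tt)), rep(0.5, 9), tolerance = 1e-6)
  }
  pa <- plan_bins(st$params$rbc, st$curve, st$events, "amplitude")
  # Inh40 sits where the rising branch crosses 40% of the range:
  # amp = -0.2 * Ap2p/2 on the way up, i.e. asin(0.2)/(2 pi) T before the
  # quarter-cycle zero crossing
  cyc <- pa$cycles[1, ]
  expected_inh40 <- cyc$start + (0.25 - asin(0.2) / (2 * pi)) * 5
  expect_equal(unname(pa$timestamps[1, "Inh40"]), expected_inh40,
               tolerance = 0.02)
  # rising and falling branch timestamps are each monotone in label order
  expect_true(all(diff(pa$timestamps[1, 1:5]) > 0))
  expect_true(all(diff(pa$timestamps[1, 6:10]) > 0))
  # every timestamp lies inside its X-ray-on interval
  iv <- st$events$intervals
  for (s in 1:3)
    expect_true(all(pa$timestamps[s, ] >= iv[s, 1] - 1e-9 &
                      pa$timestamps[s, ] <= iv[s, 2] + 1e-9))
  expect_false(any(pa$partial))
})

test_that("the RBC can steer cycle selection in multi-cycle segments", {
  # two candidate cycles inside one beam-on interval: a symmetric one and a
  # time-skewed one (early inhalation peak)
  cycle_amp <- function(u, skew = 1) -5 * cos(2 * pi * u^skew)
  t <- seq(0, 40, 0.02)
  u <- ((t + 2.5) %% 5) / 5  # valleys at 2.5, 7.5, ... (3 cycles in training)
  amp <- cycle_amp(u)
  skewed <- t >= 27.5 & t < 32.5  # one skewed cycle inside the beam window
  amp[skewed] <- cycle_amp(u[skewed], skew = 1.35)
  bc <- breathing_curve(t, amp)
  ev <- xray_events(22.5, 33)  # covers cycles [22.5, 27.5] and [27.5, 32.5]
  bc <- apply_xray_events(bc, ev)
  params <- analyze_training(bc, first_on = 20)
  # clean RBC (from the regular training cycles) picks the symmetric cycle
  plan_clean <- plan_bins(params$rbc, bc, ev, "phase")
  expect_lt(plan_clean$cycles$start[1], 27)
  # an RBC matching the skewed shape (phase 0 at its early peak) picks the
  # skewed cycle instead, which moves the phase-mode bin timestamps
  rbc_dist <- params$rbc
  uu <- seq(0, 1, length.out = 101)
  up <- 0.5^(1 / 1.35)  # peak position of the skewed cycle
  rbc_dist$amp <- cycle_amp((uu + up) %% 1, skew = 1.35)
  plan_dist <- plan_bins(rbc_dist, bc, ev, "phase")
  expect_gt(plan_dist$cycles$start[1], 27)
  expect_false(isTRUE(all.equal(plan_clean$timestamps, plan_dist$timestamps)))
})

test_that("COM evaluation reproduces the binned tumor positions", {
  st <- simulate_i4dct_study(Ap2p = 10, rate = 12, n_segments = 3)
  geom <- phantom_geometry()
  pa <- plan_bins(st$params$rbc, st$curve, st$events, "amplitude")
  tr <- evaluate_com(pa, st$curve, geom)
  # amplitude bins sample the sine at 0/20/.../100% of its range
  expected <- c(-5, -3, -1, 1, 3, 5, 3, 1, -1, -3)
  expect_equal(tr$com_mm, expected, tolerance = 0.3)
  # normalized to maximum inspiration: anchor bin at zero, others below
  expect_equal(max(tr$com_norm), 0)
  expect_equal(tr$com_norm[tr$labels == "Exh100"], 0)
  # identical plans give identical trajectories
  tr2 <- evaluate_com(pa, st$curve, geom)
  expect_identical(tr$com_mm, tr2$com_mm)
  # phase mode: inverted, anchored at maximum expiration, and symmetric
  # about its extremum for symmetric motion
  pp <- plan_bins(st$params$rbc, st$curve, st$events, "phase")
  trp <- evaluate_com(pp, st$curve, geom)
  expect_equal(min(abs(trp$com_norm)), 0)
  v <- trp$com_norm
  i0 <- which.min(v)
  mirrored <- v[((i0 - 1 + (10:1)) %% 10) + 1]
  shifted <- v[((i0 - 1 + (1:10)) %% 10) + 1]
  expect_equal(shifted[2:10], rev(mirrored[1:9]), tolerance = 0.3)
  # a threshold above the tumor HU leaves nothing to segment
  expect_error(evaluate_com(pa, st$curve, geom, threshold_hu = 100),
               "empty segmentation")
})
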
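# Independent oracles and small fixture builders used across test files.

# Brute-force discrete cross-correlation lag with parabolic interpolation of
# the peak. Returns the delay of `b` relative to `a` in seconds: positive
# when b lags a (b's features occur later).
oracle_xcorr_lag <- function(a_amp, b_amp, dt, max_lag_s) {
  K <- round(max_lag_s / dt)
  n <- length(a_amp)
  stopifnot(length(b_amp) == n, K < n - 1)
  cc <- vapply(-K:K, function(k) {
    if (k >= 0) sum(a_amp[1:(n - k)] * b_amp[(1 + k):n])
    else sum(a_amp[(1 - k):n] * b_amp[1:(n + k)])
  }, numeric(1))
  i <- which.max(cc)
  lag <- (-K:K)[i] * dt
  if (i > 1 && i < length(cc)) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (abs(denom) > 0) {
      delta <- 0.5 * (cc[i - 1] - cc[i + 1]) / denom
      lag <- lag + max(min(delta, 1), -1) * dt
    }
  }
  lag
}

# Plain sine curve fixture on the standard 20 ms grid.
sine_curve <- function(Ap2p = 10, rate = 12, duration = 60, grid_dt = 0.02) {
  generate_curve(curve_spec("sin", Ap2p = Ap2p, rate = rate,
                            duration = duration, grid_dt = grid_dt))
}

# Valley-aligned sinusoid with per-cycle periods given explicitly
# (continuous phase and slope): each cycle runs valley -> peak -> valley, so
# valley-to-valley intervals equal `periods` exactly. Used to build curves
# with one anomalous cycle or known mixed cycle lengths.
sine_with_periods <- function(periods, Ap2p = 10, grid_dt = 0.02,
                              duration = sum(periods)) {
  starts <- cumsum(c(0, periods))
  t <- seq(0, duration, by = grid_dt)
  k <- pmin(pmax(findInterval(t, starts), 1L), length(periods))
  phi <- 2 * pi * ((k - 1L) + (t - starts[k]) / periods[k])
  breathing_curve(t, -Ap2p / 2 * cos(phi))
}
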
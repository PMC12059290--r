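#' Shift a curve in time on its fixed grid
#'
#' Emulates a signal latency: the amplitude channel is shifted by `dt_ms`
#' via linear interpolation on the unchanged time grid (positive = lagging,
#' negative = ahead), with constant extension at the record edges. The
#' X-ray status channel is left untouched — the scanner's events are the
#' fixed time frame.
#'
#' @param curve a [breathing_curve()].
#' @param dt_ms signed shift in milliseconds; `|dt_ms|` must be smaller
#'   than the record duration.
#' @return The shifted curve.
#' @export
shift_curve <- function(curve, dt_ms) {
  stopifnot(inherits(curve, "breathing_curve"))
  dt <- dt_ms / 1000
  dur <- curve$t[length(curve$t)] - curve$t[1]
  if (abs(dt) >= dur)
    stop("|shift| must be smaller than the record duration", call. = FALSE)
  if (dt == 0) return(curve)
  curve$amp <- interp_lin(curve$t, curve$amp, curve$t - dt)
  curve
}

#' Sweep artificial latencies and quantify the centre-of-mass impact
#'
#' For each latency in `shifts_ms`, the breathing curve is shifted, bins
#' are re-planned against the *fixed* X-ray events, and the tumor COM
#' trajectory is evaluated against the unshifted ground-truth motion. The
#' deviation of each shifted trajectory from the unshifted reference
#' trajectory is summarized per mode. The 0 ms entry is identically zero
#' by construction (self-reference). A shift for which binning fails is
#' reported in the `note` column rather than aborting the sweep.
#'
#' @param curve the sorting [breathing_curve()] (with its beam events in
#'   the status channel or given via `events`).
#' @param params [analyze_training()] output (provides the RBC).
#' @param events [xray_events()] defining the fixed beam-on segments.
#' @param geometry a [phantom_geometry()].
#' @param shifts_ms latency set in ms; default -500, -100 to 100 in steps
#'   of 20, and +500.
#' @param modes binning modes to evaluate.
#' @param motion ground-truth tumor motion; defaults to `curve`.
#' @return A `latency_sweep` data.frame: `shift_ms`, `mode`,
#'   `mean_dev_mm`, `sd_dev_mm`, `n_bins`, `note`.
#' @export
latency_sweep <- function(curve, params, events,
                          geometry = phantom_geometry(),
                          shifts_ms = c(-500, seq(-100, 100, by = 20), 500),
                          modes = c("amplitude", "phase"),
                          motion = curve) {
  stopifnot(inherits(params, "training_params"))
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  for (mode in modes) {
    ref <- evaluate_com(plan_bins(params$rbc, curve, events, mode),
                        motion, geometry)
    for (d in shifts_ms) {
      res <- tryCatch({
        shifted <- shift_curve(curve, d)
        traj <- evaluate_com(plan_bins(params$rbc, shifted, events, mode),
                             motion, geometry)
        dev <- traj$com_norm - ref$com_norm
        list(mean = mean(dev),
             sd = if (length(dev) > 1) stats::sd(dev) else 0,
             n = length(dev), note = "")
      }, error = function(e)
        list(mean = NA_real_, sd = NA_real_, n = 0L,
             note = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        shift_ms = d, mode = mode, mean_dev_mm = res$mean,
        sd_dev_mm = res$sd, n_bins = res$n, note = res$note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("latency_sweep", class(out))
  out
}

#' Estimate the latency between two surrogate recordings
#'
#' Both curves are smoothed with a centered moving average, their
#' inhalation maxima after the first X-ray-on are refined to sub-sample
#' precision by a local quadratic fit, and maxima are matched nearest in
#' time. The reported lag is the mean of `t_max(b) - t_max(a)` over the
#' matches, in ms: a negative lag means the second curve's maxima occur
#' earlier, i.e. `b` leads `a`. Equivalently,
#' `estimate_latency(shift_curve(c, d), c)` returns approximately `-d`.
#'
#' @param a,b [breathing_curve()]s aligned to a common frame (when a curve
#'   carries no X-ray status, its full record is used).
#' @param smooth_s moving-average window, seconds (default 0.1).
#' @param fit_half_s half-width of the quadratic fit around each maximum,
#'   seconds (default 0.25).
#' @param min_prom_frac prominence fraction for peak detection.
#' @return A `latency_estimate`: `lag_ms`, `sd_ms`, `n_maxima`.
#' @export
estimate_latency <- function(a, b, smooth_s = 0.1, fit_half_s = 0.25,
                             min_prom_frac = 0.2) {
  ta <- refined_maxima(a, smooth_s, fit_half_s, min_prom_frac)
  tb <- refined_maxima(b, smooth_s, fit_half_s, min_prom_frac)
  if (length(ta) < 3 || length(tb) < 3)
    stop("need at least 3 maxima after the first X-ray-on in each curve",
         call. = FALSE)
  period <- stats::median(diff(ta))
  lags <- vapply(ta, function(x) {
    d <- tb - x
    k <- which.min(abs(d))
    if (abs(d[k]) <= period / 2) d[k] else NA_real_
  }, numeric(1))
  lags <- lags[!is.na(lags)]
  if (length(lags) < 3)
    stop("fewer than 3 matched maxima within half a period", call. = FALSE)
  structure(list(lag_ms = 1000 * mean(lags),
                 sd_ms = 1000 * (if (length(lags) > 1) stats::sd(lags) else 0),
                 n_maxima = length(lags)),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> %.1f +/- %.1f ms over %d maxima\n",
              x$lag_ms, x$sd_ms, x$n_maxima))
  invisible(x)
}

refined_maxima <- function(curve, smooth_s, fit_half_s, min_prom_frac) {
  stopifnot(inherits(curve, "breathing_curve"))
  dt <- curve_dt(curve)
  sm <- moving_average(curve$amp, max(1L, round(smooth_s / dt)))
  ext <- significant_extrema(sm, min_prom_frac * diff(range(sm)))
  pk <- ext$index[ext$type == "peak"]
  t0 <- first_rising_edge(curve)
  if (is.na(t0)) t0 <- curve$t[1]
  pk <- pk[curve$t[pk] >= t0 - 1e-9]
  half_n <- max(1L, round(fit_half_s / dt))
  vapply(pk, function(i) {
    lo <- max(1L, i - half_n); hi <- min(length(sm), i + half_n)
    x <- curve$t[lo:hi] - curve$t[i]
    y <- sm[lo:hi]
    fit <- stats::lm.fit(cbind(1, x, x^2), y)
    b1 <- fit$coefficients[2]; b2 <- fit$coefficients[3]
    if (!is.finite(b2) || b2 >= 0) return(curve$t[i])
    vx <- -b1 / (2 * b2)
    curve$t[i] + max(min(vx, fit_half_s), -fit_half_s)
  }, numeric(1))
}
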
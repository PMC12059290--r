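#' Breathing curve container
#'
#' A `breathing_curve` is the package's universal currency: a uniformly
#' sampled surrogate signal with a per-sample irradiation (X-ray-on) status.
#' Amplitudes are in mm unless `units_normalized` is `TRUE`, in which case
#' they are dimensionless (0 at the reference minimum, 1 at the following
#' maximum; see [normalize_amplitude()]).
#'
#' @param t numeric vector of sample times in seconds, strictly increasing
#'   with constant spacing.
#' @param amp numeric vector of displacement values (mm), same length as `t`,
#'   all finite.
#' @param xray_on logical vector of per-sample beam status, same length as
#'   `t`. Defaults to all-`FALSE`.
#' @param system_label free-text label of the recording system.
#' @param units_normalized logical; `TRUE` after amplitude normalization.
#' @param strict_grid enforce a uniform sample grid (the normal case). Set
#'   to `FALSE` only for raw file imports that still need
#'   [resample_curve()]; times must then still be strictly increasing.
#'
#' @return An object of class `breathing_curve`: a list with elements `t`,
#'   `amp`, `xray_on`, `system_label`, `units_normalized`.
#' @seealso [generate_curve()], [resample_curve()], [normalize_amplitude()]
#' @export
#' @examples
#' bc <- breathing_curve(t = seq(0, 1, 0.02), amp = sin(seq(0, 1, 0.02)))
#' print(bc)
breathing_curve <- function(t, amp, xray_on = NULL, system_label = "unknown",
                            units_normalized = FALSE, strict_grid = TRUE) {
  t <- as.numeric(t)
  amp <- as.numeric(amp)
  if (length(t) != length(amp))
    stop("`t` and `amp` must have the same length", call. = FALSE)
  if (is.null(xray_on)) xray_on <- rep(FALSE, length(t))
  xray_on <- as.logical(xray_on)
  if (length(xray_on) != length(t))
    stop("`xray_on` must have the same length as `t`", call. = FALSE)
  obj <- structure(
    list(t = t, amp = amp, xray_on = xray_on,
         system_label = as.character(system_label)[1],
         units_normalized = isTRUE(units_normalized)),
    class = "breathing_curve")
  validate_breathing_curve(obj, strict_grid = strict_grid)
}

#' @rdname breathing_curve
#' @param x a `breathing_curve`.
#' @export
validate_breathing_curve <- function(x, strict_grid = TRUE) {
  t <- x$t
  if (length(t) < 2) stop("breathing curve needs at least 2 samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  if (strict_grid && max(dt) - min(dt) > 1e-9)
    stop("sample times must lie on a uniform grid (spacing constant within 1e-9 s)",
         call. = FALSE)
  if (!all(is.finite(x$amp)))
    stop("amplitudes must be finite at every sample", call. = FALSE)
  if (anyNA(x$xray_on)) stop("`xray_on` must not contain NA", call. = FALSE)
  x
}

#' @export
print.breathing_curve <- function(x, ...) {
  dt <- curve_dt(x)
  cat(sprintf("<breathing_curve> %s\n", x$system_label))
  cat(sprintf("  %d samples, t = [%.3f, %.3f] s, dt = %g s\n",
              length(x$t), x$t[1], x$t[length(x$t)], dt))
  cat(sprintf("  amp range [%.3f, %.3f] %s; X-ray on for %.1f%% of samples\n",
              min(x$amp), max(x$amp),
              if (x$units_normalized) "(normalized)" else "mm",
              100 * mean(x$xray_on)))
  invisible(x)
}

#' @export
as.data.frame.breathing_curve <- function(x, ...) {
  data.frame(time_s = x$t, amplitude_mm = x$amp, xray_on = as.integer(x$xray_on))
}

#' @export
plot.breathing_curve <- function(x, ...) {
  graphics::plot(x$t, x$amp, type = "l", xlab = "time (s)",
                 ylab = if (x$units_normalized) "amplitude (norm.)" else "amplitude (mm)",
                 main = x$system_label, ...)
  if (any(x$xray_on)) {
    iv <- xray_events(x)$intervals
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(iv)))
      graphics::rect(iv[i, 1], usr[3], iv[i, 2], usr[4],
                     col = grDevices::adjustcolor("cyan", 0.2), border = NA)
  }
  invisible(x)
}

curve_dt <- function(curve) {
  stats::median(diff(curve$t))
}

curve_span <- function(curve) {
  range(curve$t)
}

#' X-ray on/off event intervals
#'
#' Extracts the ordered beam-on intervals from a curve's per-sample status
#' channel, or builds an `xray_events` object from explicit on/off times.
#' Interval edges are placed at the first sample of each on-run (rising edge)
#' and the first sample after it (falling edge).
#'
#' @param x a `breathing_curve`, or a numeric vector of on-times when
#'   `off` is given.
#' @param off numeric vector of off-times (same length as `x`) when building
#'   events directly.
#' @param source `"measured"` or `"simulated"`.
#' @return An `xray_events` object: list with `intervals` (two-column matrix
#'   `on`, `off`, seconds) and `source`.
#' @export
#' @examples
#' bc <- breathing_curve(seq(0, 1, 0.1), rep(0, 11),
#'                       xray_on = c(rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 4)))
#' xray_events(bc)$intervals
xray_events <- function(x, off = NULL, source = "measured") {
  if (inherits(x, "breathing_curve")) {
    r <- rle(x$xray_on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    on_runs <- which(r$values)
    if (length(on_runs) == 0) {
      iv <- matrix(numeric(0), ncol = 2)
    } else {
      dt <- curve_dt(x)
      on_t <- x$t[starts[on_runs]]
      off_t <- ifelse(ends[on_runs] < length(x$t),
                      x$t[pmin(ends[on_runs] + 1, length(x$t))],
                      x$t[length(x$t)] + dt)
      iv <- cbind(on_t, off_t)
    }
  } else {
    on_t <- as.numeric(x)
    off_t <- as.numeric(off)
    if (length(on_t) != length(off_t))
      stop("`x` and `off` must have the same length", call. = FALSE)
    iv <- cbind(on_t, off_t)
  }
  colnames(iv) <- c("on", "off")
  if (nrow(iv) > 0) {
    if (any(iv[, 2] <= iv[, 1]))
      stop("each X-ray interval must have off > on", call. = FALSE)
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("X-ray intervals must be non-overlapping and increasing", call. = FALSE)
  }
  structure(list(intervals = iv, source = match.arg(source, c("measured", "simulated"))),
            class = "xray_events")
}

#' @export
print.xray_events <- function(x, ...) {
  cat(sprintf("<xray_events> %d interval(s), source: %s\n",
              nrow(x$intervals), x$source))
  if (nrow(x$intervals) > 0) {
    d <- x$intervals[, 2] - x$intervals[, 1]
    cat(sprintf("  on-durations: mean %.3f s, range [%.3f, %.3f] s\n",
                mean(d), min(d), max(d)))
  }
  invisible(x)
}

#' Stamp X-ray events onto a curve's status channel
#'
#' @param curve a `breathing_curve`.
#' @param events an `xray_events` object.
#' @return The curve with `xray_on` set `TRUE` for samples inside any
#'   `[on, off)` interval.
#' @export
apply_xray_events <- function(curve, events) {
  stopifnot(inherits(curve, "breathing_curve"), inherits(events, "xray_events"))
  on <- rep(FALSE, length(curve$t))
  iv <- events$intervals
  for (i in seq_len(nrow(iv)))
    on <- on | (curve$t >= iv[i, 1] & curve$t < iv[i, 2])
  curve$xray_on <- on
  curve
}

first_rising_edge <- function(curve) {
  iv <- xray_events(curve)$intervals
  if (nrow(iv) == 0) return(NA_real_)
  iv[1, 1]
}
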
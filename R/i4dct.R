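#' Analyze the training period and derive scan parameters
#'
#' Breathing-adapted sequence scanning analyzes the 20 s of surrogate
#' signal before the first X-ray-on (the training period) to select scan
#' parameters and to build the reference breathing curve (RBC). The
#' training window must cover at least three complete breathing cycles.
#'
#' The gantry rotation time is chosen as the largest value of the discrete
#' scanner set not exceeding a quarter of the mean cycle period — a
#' documented stand-in for the vendor's unpublished mapping. The RBC is the
#' mean of the training cycles, each resampled to 101 phase samples from
#' one inhalation maximum to the next (phase 0% = start of exhalation).
#'
#' @param curve a [breathing_curve()].
#' @param first_on start of irradiation, seconds; defaults to the curve's
#'   first X-ray-on rising edge.
#' @param window_s training window length, seconds (20 by default).
#' @param rotation_set discrete set of available gantry rotation times, s.
#' @param min_cycles minimum number of complete training cycles.
#' @return A `training_params` object: `window`, `mean_cycle_s`,
#'   `mean_amp`, `amp_band` (0.7-1.3 times the mean per-cycle amplitude),
#'   `rotation_time_s`, `rbc`, `n_cycles`.
#' @export
analyze_training <- function(curve, first_on = NULL, window_s = 20,
                             rotation_set = c(0.25, 0.35, 0.5, 1.0),
                             min_cycles = 3) {
  stopifnot(inherits(curve, "breathing_curve"))
  if (is.null(first_on)) {
    first_on <- first_rising_edge(curve)
    if (is.na(first_on))
      stop("curve has no X-ray-on edge; supply `first_on`", call. = FALSE)
  }
  t0 <- first_on - window_s
  if (t0 < curve$t[1] - 1e-9)
    stop("training window extends before the start of the recording",
         call. = FALSE)
  sel <- curve$t >= t0 - 1e-9 & curve$t <= first_on + 1e-9
  win <- breathing_curve(curve$t[sel], curve$amp[sel],
                         system_label = curve$system_label)
  cs <- detect_cycles(win)
  if (nrow(cs$cycles) < min_cycles)
    stop("training window covers only ", nrow(cs$cycles),
         " complete cycle(s); at least ", min_cycles, " are required",
         call. = FALSE)
  mean_cycle <- mean(cs$cycles$end - cs$cycles$start)
  mean_amp <- mean(cs$cycles$amp)
  fit <- rotation_set[rotation_set <= mean_cycle / 4]
  rotation <- if (length(fit) > 0) max(fit) else {
    warning("no rotation time <= mean_cycle/4 available; using the fastest",
            call. = FALSE)
    min(rotation_set)
  }
  structure(list(window = c(t0, first_on), mean_cycle_s = mean_cycle,
                 mean_amp = mean_amp, amp_band = c(0.7, 1.3) * mean_amp,
                 rotation_time_s = rotation,
                 rbc = build_rbc(win, cs), n_cycles = nrow(cs$cycles)),
            class = "training_params")
}

#' @export
print.training_params <- function(x, ...) {
  cat(sprintf(paste0("<training_params> window [%.1f, %.1f] s, %d cycle(s)\n",
                     "  mean cycle %.2f s, mean amp %.2f, rotation %.2f s\n"),
              x$window[1], x$window[2], x$n_cycles, x$mean_cycle_s,
              x$mean_amp, x$rotation_time_s))
  invisible(x)
}

# Reference breathing curve: mean over maximum-to-maximum training cycles,
# 101 phase samples (0% = start of exhalation = inhalation maximum).
build_rbc <- function(win, cs, n_phase = 101) {
  pk <- cs$peaks$time
  if (length(pk) < 2)
    stop("need at least two inhalation maxima to build the RBC", call. = FALSE)
  phase <- seq(0, 100, length.out = n_phase)
  mat <- vapply(seq_len(length(pk) - 1), function(j) {
    ts <- seq(pk[j], pk[j + 1], length.out = n_phase)
    interp_lin(win$t, win$amp, ts)
  }, numeric(n_phase))
  structure(list(phase = phase, amp = rowMeans(mat),
                 source_cycles = seq_len(length(pk) - 1)),
            class = "rbc")
}

#' @export
print.rbc <- function(x, ...) {
  cat(sprintf("<rbc> %d phase samples over %d cycle(s); amp range [%.2f, %.2f]\n",
              length(x$phase), length(x$source_cycles), min(x$amp), max(x$amp)))
  invisible(x)
}

#' Simulate intelligent X-ray on/off trigger selection
#'
#' A curve-level state machine standing in for the vendor's proprietary
#' phase-space trigger constraints (which are not modelled here):
#'
#' * WAIT — couch static, beam off; arm at the first exhalation valley
#'   after readiness.
#' * ON — beam on from that valley until a complete, *valid* cycle
#'   (valley-to-valley) plus the gantry rotation time is covered. A cycle
#'   is valid when its amplitude lies inside the training amplitude band
#'   and its period deviates less than `period_tol` from the training mean;
#'   invalid cycles keep the beam on until the next valid complete cycle.
#' * OFF — the couch moves one increment during `move_duration`; then the
#'   next segment is armed. Repeated `n_segments` times.
#'
#' @param curve a [breathing_curve()] extending beyond the training window.
#' @param params [analyze_training()] output.
#' @param n_segments number of beam-on segments (couch positions).
#' @param move_duration couch move time between segments, seconds.
#' @param period_tol relative period tolerance for cycle validity.
#' @return An [xray_events()] object (`source = "simulated"`) with one
#'   interval per segment; attribute `"segments"` records per-segment
#'   cycle counts.
#' @export
simulate_triggers <- function(curve, params, n_segments, move_duration = 1,
                              period_tol = 0.3) {
  stopifnot(inherits(curve, "breathing_curve"),
            inherits(params, "training_params"))
  if (n_segments == 0)
    return(xray_events(numeric(0), numeric(0), source = "simulated"))
  cs <- detect_cycles(curve)
  cy <- cs$cycles
  valid <- abs((cy$end - cy$start) - params$mean_cycle_s) <=
    period_tol * params$mean_cycle_s &
    cy$amp >= params$amp_band[1] & cy$amp <= params$amp_band[2]
  t_ready <- params$window[2]
  on <- off <- numeric(n_segments)
  n_cycles_used <- integer(n_segments)
  for (s in seq_len(n_segments)) {
    j <- which(cy$start > t_ready - 1e-9)
    if (length(j) == 0)
      stop("curve ends before segment ", s, " can be armed", call. = FALSE)
    j <- j[1]
    on[s] <- cy$start[j]
    k <- j
    while (k <= nrow(cy) && !valid[k]) k <- k + 1L
    if (k > nrow(cy) || cy$end[k] > curve$t[length(curve$t)])
      stop("curve ends before segment ", s, " sees a valid complete cycle",
           call. = FALSE)
    off[s] <- cy$end[k] + params$rotation_time_s
    n_cycles_used[s] <- k - j + 1L
    t_ready <- off[s] + move_duration
  }
  ev <- xray_events(on, off, source = "simulated")
  attr(ev, "segments") <- data.frame(on = on, off = off,
                                     duration = off - on,
                                     cycles = n_cycles_used)
  ev
}

#' Compare two sets of X-ray trigger events
#'
#' Differences are computed as `b - a` over the matched prefix of the two
#' interval lists (with a warning when the counts differ).
#'
#' @param a,b [xray_events()] objects (both non-empty).
#' @return A list: `on_diff_mean/sd`, `off_diff_mean/sd`,
#'   `dur_diff_mean/sd` (seconds), `dur_a_mean/sd`, `dur_b_mean/sd`, `n`.
#' @export
compare_triggers <- function(a, b) {
  ia <- a$intervals; ib <- b$intervals
  if (nrow(ia) == 0 || nrow(ib) == 0)
    stop("cannot compare empty trigger sets", call. = FALSE)
  if (nrow(ia) != nrow(ib))
    warning("interval counts differ (", nrow(ia), " vs ", nrow(ib),
            "); comparing the matched prefix", call. = FALSE)
  n <- min(nrow(ia), nrow(ib))
  ia <- ia[seq_len(n), , drop = FALSE]; ib <- ib[seq_len(n), , drop = FALSE]
  da <- ia[, 2] - ia[, 1]; db <- ib[, 2] - ib[, 1]
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(on_diff_mean = mean(ib[, 1] - ia[, 1]), on_diff_sd = sd0(ib[, 1] - ia[, 1]),
       off_diff_mean = mean(ib[, 2] - ia[, 2]), off_diff_sd = sd0(ib[, 2] - ia[, 2]),
       dur_diff_mean = mean(db - da), dur_diff_sd = sd0(db - da),
       dur_a_mean = mean(da), dur_a_sd = sd0(da),
       dur_b_mean = mean(db), dur_b_sd = sd0(db), n = n)
}

# First time at which the sampled segment crosses `level`, moving in
# `direction` (+1 rising, -1 falling); linear interpolation between samples.
crossing_time <- function(ts, ys, level, direction) {
  dy <- ys - level
  for (i in seq_len(length(ys) - 1)) {
    if (direction > 0 && dy[i] <= 0 && dy[i + 1] >= 0 ||
        direction < 0 && dy[i] >= 0 && dy[i + 1] <= 0) {
      if (dy[i + 1] == dy[i]) return(ts[i])
      return(ts[i] + (ts[i + 1] - ts[i]) * (0 - dy[i]) / (dy[i + 1] - dy[i]))
    }
  }
  NA_real_
}

amplitude_bin_labels <- function() {
  c("Inh0", "Inh20", "Inh40", "Inh60", "Inh80",
    "Exh100", "Exh80", "Exh60", "Exh40", "Exh20")
}

phase_bin_labels <- function() {
  paste0(seq(0, 90, 10), "%")
}

#' Place amplitude- or phase-based reconstruction bins
#'
#' For every beam-on segment, the complete valley-to-valley cycle best
#' matching the reference breathing curve (minimal RMS distance after
#' normalizing both to the unit range) is selected, and ten bin timestamps
#' are placed on it:
#'
#' * amplitude mode — `Inh0` to `Inh80` where the rising branch first
#'   crosses 0/20/40/60/80% of the cycle's amplitude range, and `Exh100` to
#'   `Exh20` where the falling branch crosses 100/80/60/40/20%;
#' * phase mode — `0%` to `90%` at tenths of the cycle duration measured
#'   from the inhalation maximum (start of exhalation); timestamps past the
#'   covered cycle end are wrapped back by one period so every timestamp
#'   stays inside the covered cycle.
#'
#' When a segment contains no fully covered cycle (as can happen for
#' strongly time-shifted curves against fixed beam events), the best cycle
#' overlapping the segment by at least `min_overlap` is used and the
#' segment is flagged as partial.
#'
#' @param rbc the reference breathing curve ([analyze_training()]`$rbc`).
#' @param curve the sorting [breathing_curve()].
#' @param events [xray_events()] with one interval per segment.
#' @param mode `"amplitude"` or `"phase"`.
#' @param min_overlap minimum covered fraction for the partial-cycle
#'   fallback.
#' @return A `binning_plan`: `mode`, `labels` (length 10), `timestamps`
#'   (matrix segments x 10), `cycles` (per-segment start/peak/end),
#'   `partial` (logical per segment).
#' @export
plan_bins <- function(rbc, curve, events, mode = c("amplitude", "phase"),
                      min_overlap = 0.7) {
  mode <- match.arg(mode)
  stopifnot(inherits(rbc, "rbc"), inherits(curve, "breathing_curve"))
  iv <- events$intervals
  if (nrow(iv) == 0) stop("no X-ray-on segments", call. = FALSE)
  cs <- detect_cycles(curve)
  cy <- cs$cycles
  labels <- if (mode == "amplitude") amplitude_bin_labels() else phase_bin_labels()
  ts_mat <- matrix(NA_real_, nrow = nrow(iv), ncol = 10,
                   dimnames = list(NULL, labels))
  chosen <- data.frame(start = numeric(nrow(iv)), peak = numeric(nrow(iv)),
                       end = numeric(nrow(iv)))
  partial <- logical(nrow(iv))
  rbc_ref <- rbc_valley_form(rbc)
  for (s in seq_len(nrow(iv))) {
    inside <- which(cy$start >= iv[s, 1] - 1e-6 & cy$end <= iv[s, 2] + 1e-6)
    cand <- inside
    if (length(cand) == 0) {
      ov <- (pmin(cy$end, iv[s, 2]) - pmax(cy$start, iv[s, 1])) /
        (cy$end - cy$start)
      cand <- which(ov >= min_overlap)
      if (length(cand) == 0)
        stop("X-ray-on segment ", s, " contains no complete breathing cycle",
             call. = FALSE)
      partial[s] <- TRUE
    }
    score <- vapply(cand, function(j)
      cycle_rbc_distance(curve, cy[j, ], rbc_ref), numeric(1))
    j <- cand[which.min(score)]
    chosen[s, ] <- cy[j, c("start", "peak", "end")]
    ts_mat[s, ] <- bin_timestamps(curve, cy[j, ], mode)
  }
  structure(list(mode = mode, labels = labels, timestamps = ts_mat,
                 cycles = chosen, partial = partial),
            class = "binning_plan")
}

#' @export
print.binning_plan <- function(x, ...) {
  cat(sprintf("<binning_plan> %s mode, %d segment(s)%s\n", x$mode,
              nrow(x$timestamps),
              if (any(x$partial)) sprintf(" (%d partial)", sum(x$partial)) else ""))
  print(round(x$timestamps, 3))
  invisible(x)
}

# RBC rotated to start at its minimum (valley-to-valley form) and scaled to
# the unit range, for comparison against valley-to-valley cycles.
rbc_valley_form <- function(rbc, n = 101) {
  vals <- rbc$amp[-length(rbc$amp)]  # drop duplicated endpoint
  i0 <- which.min(vals)
  m <- length(vals)
  rot <- vals[((i0 - 1 + seq_len(m) - 1) %% m) + 1]
  rot <- c(rot, rot[1])
  rot <- stats::approx(seq_along(rot), rot, n = n)$y
  (rot - min(rot)) / max(diff(range(rot)), .Machine$double.eps)
}

cycle_rbc_distance <- function(curve, cyc, rbc_ref) {
  ts <- seq(cyc$start, cyc$end, length.out = length(rbc_ref))
  ys <- interp_lin(curve$t, curve$amp, ts)
  rng <- diff(range(ys))
  if (rng <= 0) return(Inf)
  ys <- (ys - min(ys)) / rng
  sqrt(mean((ys - rbc_ref)^2))
}

bin_timestamps <- function(curve, cyc, mode) {
  if (mode == "phase") {
    Tc <- cyc$end - cyc$start
    tk <- cyc$peak + seq(0, 0.9, 0.1) * Tc
    over <- tk > cyc$end + 1e-9
    tk[over] <- tk[over] - Tc
    return(tk)
  }
  sel <- which(curve$t >= cyc$start - 1e-9 & curve$t <= cyc$end + 1e-9)
  ts <- curve$t[sel]; ys <- curve$amp[sel]
  hi <- max(ys, interp_lin(curve$t, curve$amp, cyc$peak))
  rise_sel <- ts <= cyc$peak + 1e-9
  rise_t <- c(ts[rise_sel], cyc$peak)
  rise_y <- c(ys[rise_sel], hi)
  fall_sel <- ts >= cyc$peak - 1e-9
  fall_t <- c(cyc$peak, ts[fall_sel])
  fall_y <- c(hi, ys[fall_sel])
  # bin levels are taken per branch (inhalation range for Inh bins,
  # exhalation range for Exh bins) so that every crossing exists even for
  # cycles with unequal flanking valleys
  level <- function(f, lo) if (f == 0) lo else if (f == 1) hi else lo + f * (hi - lo)
  lo_r <- min(rise_y); lo_f <- min(fall_y)
  inh <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(f)
    crossing_time(rise_t, rise_y, level(f, lo_r), +1), numeric(1))
  exh <- vapply(c(1, 0.8, 0.6, 0.4, 0.2), function(f)
    crossing_time(fall_t, fall_y, level(f, lo_f), -1), numeric(1))
  c(inh, exh)
}

#' Evaluate image quality through the tumor centre of mass
#'
#' For each bin of a [plan_bins()] plan, the tumor position is the (true)
#' motion curve evaluated at the bin's timestamps, averaged over segments;
#' a phantom volume is rendered at that position, segmented by HU
#' thresholding, and its inferior-superior centre of mass computed. The
#' trajectory is normalized to maximum inspiration for amplitude-based
#' binning and to maximum expiration — and inverted in amplitude — for
#' phase-based binning.
#'
#' @param plan a `binning_plan`.
#' @param motion the ground-truth tumor motion as a [breathing_curve()]
#'   covering all timestamps (amplitude in mm = inferior-superior offset).
#' @param geometry a [phantom_geometry()].
#' @param threshold_hu segmentation threshold; defaults to the geometry's.
#' @return A `com_trajectory`: `labels`, `positions_mm` (mean tumor
#'   position per bin), `com_mm` (raw COM), `com_norm` (normalized,
#'   inverted for phase mode), `normalization`, `inverted`, `mode`.
#' @export
evaluate_com <- function(plan, motion, geometry = phantom_geometry(),
                         threshold_hu = geometry$threshold_hu) {
  stopifnot(inherits(plan, "binning_plan"), inherits(motion, "breathing_curve"))
  ts <- plan$timestamps
  if (min(ts) < motion$t[1] - 1e-9 || max(ts) > motion$t[length(motion$t)] + 1e-9)
    stop("motion curve does not cover all bin timestamps", call. = FALSE)
  pos_mat <- matrix(interp_lin(motion$t, motion$amp, as.numeric(ts)),
                    nrow = nrow(ts), ncol = ncol(ts))
  positions <- colMeans(pos_mat)
  series <- render_phantom_series(positions, geometry, bin_labels = plan$labels)
  com <- vapply(series$volumes, com_is, numeric(1), geometry = geometry,
                threshold_hu = threshold_hu)
  if (plan$mode == "amplitude") {
    anchor <- which.max(com)  # maximum inspiration
    norm <- com - com[anchor]
    normalization <- "max_inspiration"
    inverted <- FALSE
  } else {
    anchor <- which.min(com)  # maximum expiration
    norm <- -(com - com[anchor])
    normalization <- "max_expiration"
    inverted <- TRUE
  }
  structure(list(labels = plan$labels, positions_mm = positions,
                 com_mm = com, com_norm = norm,
                 normalization = normalization, inverted = inverted,
                 mode = plan$mode),
            class = "com_trajectory")
}

#' @export
print.com_trajectory <- function(x, ...) {
  cat(sprintf("<com_trajectory> %s mode, normalized to %s%s\n", x$mode,
              x$normalization, if (x$inverted) ", inverted" else ""))
  print(round(stats::setNames(x$com_norm, x$labels), 3))
  invisible(x)
}
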
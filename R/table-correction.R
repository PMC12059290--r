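#' Detect patch-propagation peak artifacts in a surface-system curve
#'
#' Surface cameras correct for couch motion by propagating their tracked
#' patch at each table increment, which leaves a narrow peak artifact in
#' the breathing curve inside the X-ray-off gap following each beam-on
#' segment. Detection is anchored at the X-ray-off edges (the propagation
#' is triggered by the end of acquisition at a table position): within each
#' window `[off_k, off_k + artifact_width]` the excursion above the local
#' linear bridge is measured, and an artifact is recorded when
#'
#' * its rate of change exceeds `slope_factor` times the maximum
#'   physiological slope observed in the training region (before the first
#'   X-ray-on), and
#' * its height exceeds `prom_factor` times the breathing maximum of the
#'   immediately preceding beam-on segment (max minus median over the
#'   segment).
#'
#' For each artifact a scaling factor is derived as artifact height divided
#' by that preceding breathing maximum — the quantity the table-motion
#' correction multiplies the couch profile with.
#'
#' @param curve the surface-system [breathing_curve()].
#' @param events [xray_events()] (typically from the curve's own status
#'   channel).
#' @param artifact_width expected artifact window width, seconds; a system
#'   characteristic like the fixed couch increment.
#' @param slope_factor multiple of the training-region maximum slope an
#'   artifact must exceed.
#' @param prom_factor minimum artifact height as a fraction of the
#'   preceding breathing maximum.
#' @return A list of `artifact_event` objects (possibly empty), each with
#'   `onset`, `peak_time`, `height`, `preceding_max`, `scale_factor`,
#'   `xray_segment_index`, `window` (start/end times).
#' @export
detect_artifacts <- function(curve, events = xray_events(curve),
                             artifact_width = 0.3, slope_factor = 1.5,
                             prom_factor = 0.25) {
  stopifnot(inherits(curve, "breathing_curve"))
  iv <- events$intervals
  if (nrow(iv) == 0) stop("no X-ray events", call. = FALSE)
  t <- curve$t; amp <- curve$amp
  dt <- curve_dt(curve)
  # physiological slope bound from the pre-irradiation training region
  train <- t < iv[1, 1] - 1e-9
  if (sum(train) < 10) train <- t < iv[1, 2]  # degenerate: fall back
  max_slope <- max(abs(diff(amp[train]))) / dt
  bound <- slope_factor * max_slope
  out <- list()
  n_gaps <- nrow(iv) - 1L
  for (k in seq_len(max(n_gaps, 0))) {
    onset <- iv[k, 2]
    wend <- onset + artifact_width
    if (wend >= iv[k + 1, 1]) wend <- iv[k + 1, 1] - dt
    inside <- which(t >= onset - 1e-9 & t <= wend + 1e-9)
    if (length(inside) < 3) next
    pre <- min(inside) - 1L
    post <- max(inside) + 1L
    if (pre < 1 || post > length(t)) next
    slopes <- abs(diff(amp[pre:post])) / dt
    if (max(slopes) <= bound) next
    bridge <- interp_lin(c(t[pre], t[post]), c(amp[pre], amp[post]), t[inside])
    excess <- amp[inside] - bridge
    peak_i <- which.max(excess)
    height <- excess[peak_i]
    if (height <= 0) next
    pm <- preceding_breathing_max(t, amp, events, onset)
    if (pm <= 0) {
      warning("non-positive preceding breathing maximum before gap ", k,
              "; artifact skipped", call. = FALSE)
      next
    }
    if (height < prom_factor * pm) next
    out[[length(out) + 1L]] <- structure(
      list(onset = onset, peak_time = t[inside][peak_i], height = height,
           preceding_max = pm, scale_factor = height / pm,
           xray_segment_index = k, window = c(t[pre], t[post])),
      class = "artifact_event")
  }
  out
}

#' @export
print.artifact_event <- function(x, ...) {
  cat(sprintf(
    "<artifact_event> after segment %d: onset %.2f s, height %.2f mm, scale %.3f\n",
    x$xray_segment_index, x$onset, x$height, x$scale_factor))
  invisible(x)
}

#' Remove the surface system's internal table-motion correction
#'
#' Excises each detected peak artifact by replacing the samples inside its
#' window with the straight line joining the samples just outside it, so
#' the curve rejoins its local baseline. Artifact windows must not overlap.
#'
#' @param curve the surface-system [breathing_curve()].
#' @param artifacts list of artifact events from [detect_artifacts()].
#' @return The curve with artifacts excised.
#' @export
strip_system_correction <- function(curve, artifacts) {
  stopifnot(inherits(curve, "breathing_curve"))
  if (length(artifacts) == 0) return(curve)
  wins <- t(vapply(artifacts, function(a) a$window, numeric(2)))
  ord <- order(wins[, 1])
  wins <- wins[ord, , drop = FALSE]
  if (nrow(wins) > 1 && any(wins[-1, 1] < wins[-nrow(wins), 2]))
    stop("overlapping artifact windows", call. = FALSE)
  amp <- curve$amp
  for (i in seq_len(nrow(wins))) {
    inside <- which(curve$t > wins[i, 1] & curve$t < wins[i, 2])
    if (length(inside) == 0) next
    pre <- min(inside) - 1L
    post <- max(inside) + 1L
    amp[inside] <- interp_lin(c(curve$t[pre], curve$t[post]),
                              c(amp[pre], amp[post]), curve$t[inside])
  }
  curve$amp <- amp
  curve
}

#' Add the scaled couch profile back to a stripped surface curve
#'
#' The retrospective table-motion correction: for each beam-on segment k
#' that is followed by a couch step, the step's displacement change —
#' taken from the independently measured table profile and multiplied by
#' the artifact's scaling factor — is added cumulatively to all samples
#' from the end of that segment onward. This cancels the amplitude scale
#' drift the surface system accumulates as the patch travels deeper into
#' the gantry. Samples before the first X-ray-off edge are never modified.
#'
#' @param curve the stripped curve (see [strip_system_correction()]).
#' @param profile the measured `table_profile`.
#' @param artifacts artifact events carrying the per-step scaling factors.
#' @param events [xray_events()] used to associate couch steps with beam-on
#'   segments.
#' @return The corrected [breathing_curve()] (label suffixed
#'   `"_corrected"`).
#' @export
apply_table_correction <- function(curve, profile, artifacts,
                                   events = xray_events(curve)) {
  stopifnot(inherits(curve, "breathing_curve"), inherits(profile, "table_profile"))
  amp <- curve$amp
  onsets <- profile$move_onsets
  deltas <- profile$step_deltas
  if (length(onsets) > 0) {
    art_seg <- vapply(artifacts, function(a) a$xray_segment_index, integer(1))
    iv <- events$intervals
    for (k in seq_along(onsets)) {
      # which inter-segment gap contains this couch move? (tolerate edges
      # snapped to the sample grid)
      gap <- which(iv[, 2] <= onsets[k] + curve_dt(curve) + 1e-9)
      if (length(gap) == 0)
        stop("couch step ", k, " precedes the first X-ray-on segment",
             call. = FALSE)
      gap <- gap[length(gap)]
      m <- which(art_seg == gap)
      if (length(m) == 0)
        stop("no artifact (and hence no scaling factor) found for the couch ",
             "step after X-ray-on segment ", gap, call. = FALSE)
      a <- artifacts[[m[1]]]
      amp[curve$t >= a$onset - 1e-9] <- amp[curve$t >= a$onset - 1e-9] +
        a$scale_factor * deltas[k]
    }
    # rejoin across the artifact windows, which now contain the stale bridge
    tmp <- curve; tmp$amp <- amp
    tmp <- strip_system_correction(tmp, artifacts)
    amp <- tmp$amp
  }
  curve$amp <- amp
  curve$system_label <- paste0(curve$system_label, "_corrected")
  curve
}

#' Correct a surface-system curve for table motion
#'
#' Convenience wrapper running [detect_artifacts()],
#' [strip_system_correction()] and [apply_table_correction()] in sequence.
#'
#' @inheritParams detect_artifacts
#' @inheritParams apply_table_correction
#' @return A list with `curve` (the corrected curve) and `artifacts`.
#' @export
correct_surface_curve <- function(curve, profile, events = xray_events(curve),
                                  artifact_width = 0.3, slope_factor = 1.5,
                                  prom_factor = 0.25) {
  arts <- detect_artifacts(curve, events, artifact_width = artifact_width,
                           slope_factor = slope_factor,
                           prom_factor = prom_factor)
  stripped <- strip_system_correction(curve, arts)
  corrected <- apply_table_correction(stripped, profile, arts, events)
  list(curve = corrected, artifacts = arts)
}

#' Subtract the couch-tool track from the phantom-tool track
#'
#' A side-mounted reference tracker follows two tools — one on the moving
#' phantom (or patient) and one on the couch — so that couch motion can be
#' subtracted sample-wise from the phantom motion.
#'
#' @param phantom_track,table_track [breathing_curve()]s on a common grid.
#' @return A [breathing_curve()] with `amp = phantom - table`.
#' @export
subtract_reference_tool <- function(phantom_track, table_track) {
  stopifnot(inherits(phantom_track, "breathing_curve"),
            inherits(table_track, "breathing_curve"))
  if (length(phantom_track$t) != length(table_track$t) ||
      max(abs(phantom_track$t - table_track$t)) > 1e-9)
    stop("phantom and table tracks must share one time grid", call. = FALSE)
  out <- phantom_track
  out$amp <- phantom_track$amp - table_track$amp
  out$system_label <- paste0(phantom_track$system_label, "-",
                             table_track$system_label)
  out
}
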
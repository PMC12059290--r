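#' Synthetic breathing-curve specification
#'
#' Describes a ground-truth breathing waveform on a uniform time grid. Two
#' waveform families are supported: a plain sinusoid,
#' \deqn{\zeta(t) = \frac{A_{p2p}}{2}\,\sin(2\pi t/T_{cycle}),}
#' and the end-exhale-weighted
#' \deqn{\zeta(t) = \frac{A_{p2p}}{2}\,\cos^6(2\pi t/T_{cycle}),}
#' which is non-negative and rests near 0 (the exhale plateau) for most of
#' the cycle. `Tcycle = 60/rate` seconds. Per-cycle multiplicative Gaussian
#' jitter factors (truncated at three standard deviations) emulate
#' amplitude and frequency irregularity.
#'
#' The design space studied with this generator spans peak-to-peak
#' amplitudes of 2–20 mm and breathing rates of 6–20 breaths per minute;
#' values outside that range are accepted with a warning.
#'
#' @param waveform `"sin"` or `"cos6"`.
#' @param Ap2p peak-to-peak amplitude in mm (> 0).
#' @param rate breathing rate in breaths per minute (> 0).
#' @param duration total signal length in seconds; must be at least three
#'   cycle periods.
#' @param grid_dt sample spacing in seconds (default 0.020, the standard
#'   surrogate export grid).
#' @param amp_jitter relative per-cycle amplitude variation (fraction,
#'   standard deviation of the multiplicative factor; 0 = strictly periodic).
#' @param rate_jitter relative per-cycle period variation (fraction).
#' @param seed integer RNG seed for the jitter draws.
#' @return A `curve_spec` object.
#' @export
#' @examples
#' spec <- curve_spec("sin", Ap2p = 10, rate = 12, duration = 60)
#' bc <- generate_curve(spec)
#' max(bc$amp)  # Ap2p / 2
curve_spec <- function(waveform = c("sin", "cos6"), Ap2p, rate, duration,
                       grid_dt = 0.020, amp_jitter = 0, rate_jitter = 0,
                       seed = NULL) {
  waveform <- match.arg(waveform)
  if (Ap2p <= 0) stop("`Ap2p` must be positive", call. = FALSE)
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  if (Ap2p < 2 || Ap2p > 20)
    warning("Ap2p = ", Ap2p, " mm is outside the 2-20 mm design space",
            call. = FALSE)
  if (rate < 6 || rate > 20)
    warning("rate = ", rate, " BPM is outside the 6-20 BPM design space",
            call. = FALSE)
  if (grid_dt <= 0) stop("`grid_dt` must be positive", call. = FALSE)
  Tcycle <- 60 / rate
  if (duration < 3 * Tcycle)
    stop("`duration` must be at least 3 cycle periods (", 3 * Tcycle, " s)",
         call. = FALSE)
  if (amp_jitter < 0 || rate_jitter < 0)
    stop("jitter fractions must be non-negative", call. = FALSE)
  structure(list(waveform = waveform, Ap2p = Ap2p, rate = rate,
                 Tcycle = Tcycle, duration = duration, grid_dt = grid_dt,
                 amp_jitter = amp_jitter, rate_jitter = rate_jitter,
                 seed = seed),
            class = "curve_spec")
}

#' Read / write a curve specification
#'
#' Specifications are stored as YAML or JSON with the field names of
#' [curve_spec()] (`waveform`, `Ap2p`, `rate`, `duration`, `grid_dt`,
#' `amp_jitter`, `rate_jitter`, `seed`).
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return A `curve_spec` object.
#' @export
read_curve_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported spec extension: .", ext, call. = FALSE)
  do.call(curve_spec, lst[intersect(names(lst),
          c("waveform", "Ap2p", "rate", "duration", "grid_dt",
            "amp_jitter", "rate_jitter", "seed"))])
}

#' @rdname read_curve_spec
#' @param spec a `curve_spec`.
#' @export
write_curve_spec <- function(spec, path) {
  lst <- spec[c("waveform", "Ap2p", "rate", "duration", "grid_dt",
                "amp_jitter", "rate_jitter", "seed")]
  lst <- lst[!vapply(lst, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path)
  else if (ext == "json") jsonlite::write_json(lst, path, auto_unbox = TRUE)
  else stop("unsupported spec extension: .", ext, call. = FALSE)
  invisible(path)
}

waveform_fun <- function(waveform) {
  switch(waveform,
         sin = function(phi) sin(phi),
         cos6 = function(phi) cos(phi)^6,
         stop("unknown waveform: ", waveform, call. = FALSE))
}

#' Generate a ground-truth breathing curve
#'
#' Evaluates the waveform of a [curve_spec()] on its uniform grid. With
#' non-zero jitter, each cycle draws a multiplicative amplitude factor
#' `~ N(1, amp_jitter)` and period factor `~ N(1, rate_jitter)` (both
#' truncated at +/- 3 standard deviations); the waveform is evaluated
#' piecewise per cycle with continuous phase, and the amplitude envelope is
#' interpolated linearly between cycle midpoints so that the signal has no
#' jumps.
#'
#' @param spec a `curve_spec`.
#' @return A [breathing_curve()] with `xray_on` all-`FALSE` and
#'   `system_label = "truth"`.
#' @export
generate_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  t <- seq(0, spec$duration, by = spec$grid_dt)
  f <- waveform_fun(spec$waveform)
  A <- spec$Ap2p / 2
  if (spec$amp_jitter == 0 && spec$rate_jitter == 0) {
    amp <- A * f(2 * pi * t / spec$Tcycle)
  } else {
    n_cycles <- ceiling(spec$duration / spec$Tcycle * 2) + 4L
    draws <- with_seed(spec$seed %||% 0L, {
      pf <- stats::rnorm(n_cycles, 1, spec$rate_jitter)
      af <- stats::rnorm(n_cycles, 1, spec$amp_jitter)
      list(pf = pmin(pmax(pf, 1 - 3 * spec$rate_jitter), 1 + 3 * spec$rate_jitter),
           af = pmin(pmax(af, 1 - 3 * spec$amp_jitter), 1 + 3 * spec$amp_jitter))
    })
    periods <- spec$Tcycle * draws$pf
    starts <- cumsum(c(0, periods))
    # continuous phase: cycle k spans one full 2*pi
    k <- findInterval(t, starts, rightmost.closed = FALSE)
    k <- pmin(pmax(k, 1L), n_cycles)
    phi <- 2 * pi * ((k - 1L) + (t - starts[k]) / periods[k])
    mids <- starts[seq_len(n_cycles)] + periods / 2
    envelope <- interp_lin(mids, draws$af, t)
    amp <- A * envelope * f(phi)
  }
  breathing_curve(t, amp, system_label = "truth")
}

#' Table (couch) motion profile
#'
#' A monotone non-decreasing staircase of longitudinal couch positions with
#' linear ramps, as used in 4DCT sequence scanning with a fixed table
#' increment (34.5 mm by default).
#'
#' `generate_table_profile()` builds a regular cadence: plateau of `dwell`
#' seconds, then a ramp of `move_duration` seconds rising one `step_size`,
#' repeated `n_steps` times, with a closing plateau.
#' `table_profile_from_events()` instead starts one ramp at the end (off
#' edge) of each of the first `n_steps` X-ray-on intervals, matching the
#' sequence-scan timing in which the couch moves between beam-on segments.
#'
#' @param n_steps number of couch increments (>= 1).
#' @param dwell plateau duration between moves, seconds (> 0).
#' @param move_duration duration of each ramp, seconds.
#' @param step_size couch increment in mm (default 34.5).
#' @param grid_dt sample spacing, seconds.
#' @return A `table_profile`: list with `t`, `displacement` (mm),
#'   `step_size`, `move_duration`, `move_onsets`, `step_deltas`.
#' @export
#' @examples
#' tp <- generate_table_profile(3, dwell = 8)
#' max(tp$displacement)  # 103.5
generate_table_profile <- function(n_steps, dwell, move_duration = 1,
                                   step_size = 34.5, grid_dt = 0.020) {
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  if (dwell <= 0) stop("`dwell` must be positive", call. = FALSE)
  if (step_size <= 0) stop("`step_size` must be positive", call. = FALSE)
  if (move_duration <= 0) stop("`move_duration` must be positive", call. = FALSE)
  onsets <- dwell + (seq_len(n_steps) - 1) * (dwell + move_duration)
  total <- n_steps * (dwell + move_duration) + dwell
  t <- seq(0, total, by = grid_dt)
  table_profile_build(t, onsets, rep(step_size, n_steps), step_size,
                      move_duration)
}

#' @rdname generate_table_profile
#' @param events an [xray_events()] object; ramps start at the off edges of
#'   its first `n_steps` intervals (all gaps when `n_steps` is missing).
#' @param span numeric length-2, time range the profile must cover.
#' @export
table_profile_from_events <- function(events, span, n_steps = NULL,
                                      move_duration = 1, step_size = 34.5,
                                      grid_dt = 0.020) {
  iv <- events$intervals
  if (is.null(n_steps)) n_steps <- max(nrow(iv) - 1L, 0L)
  if (n_steps < 1) stop("need at least one gap between X-ray segments", call. = FALSE)
  if (n_steps > nrow(iv))
    stop("more steps requested than X-ray segments available", call. = FALSE)
  onsets <- iv[seq_len(n_steps), 2]
  t <- seq(span[1], span[2], by = grid_dt)
  table_profile_build(t, onsets, rep(step_size, n_steps), step_size,
                      move_duration)
}

table_profile_build <- function(t, move_onsets, step_deltas, step_size,
                                move_duration) {
  disp <- rep(0, length(t))
  for (k in seq_along(move_onsets)) {
    o <- move_onsets[k]
    ramp <- pmin(pmax((t - o) / move_duration, 0), 1)
    disp <- disp + step_deltas[k] * ramp
  }
  structure(list(t = t, displacement = disp, step_size = step_size,
                 move_duration = move_duration, move_onsets = move_onsets,
                 step_deltas = step_deltas),
            class = "table_profile")
}

#' @export
print.table_profile <- function(x, ...) {
  cat(sprintf("<table_profile> %d step(s) of %.1f mm, final displacement %.1f mm\n",
              length(x$move_onsets), x$step_size, max(x$displacement)))
  cat(sprintf("  move onsets (s): %s\n", paste(round(x$move_onsets, 2), collapse = ", ")))
  invisible(x)
}

#' Surrogate-system emulation specification
#'
#' Parameters of the measurement chain that turns a ground-truth breathing
#' curve into a surrogate recording: a signal delay (`latency`), a
#' multiplicative gain (`amp_scale`), additive Gaussian noise, and — for
#' non-table-mounted systems during sequence scanning — table-motion
#' contamination. After each couch step the recorded baseline drops by
#' `contamination_gain * step_size` (amplitude scale drift as the tracked
#' patch travels into the gantry), and the system's internal patch
#' propagation replaces the signal during the move with a narrow triangular
#' peak artifact.
#'
#' `artifact_heights = "auto"` sets each spike height to
#' `contamination_gain` times the preceding breathing maximum (estimated
#' over the preceding beam-on segment as max minus median), mirroring the
#' observation that the spike height relative to the preceding maximum
#' encodes the system's scaling factor.
#'
#' `surface_espec()` is the surface-camera preset: gain 0.9356 (the
#' corrected surface system underestimated amplitude maxima by 6.44% in the
#' reference measurements), full table contamination, auto spike heights.
#'
#' @param latency signal delay in seconds relative to ground truth
#'   (negative = system ahead).
#' @param amp_scale multiplicative gain.
#' @param noise_sd additive Gaussian noise standard deviation, mm.
#' @param artifact_heights `"auto"`, `NULL` (no artifacts), or a numeric
#'   vector with one spike height (mm) per table step.
#' @param artifact_width spike width in seconds (> 0).
#' @param contamination_gain fraction of each couch displacement leaking
#'   into the measured axis.
#' @param seed integer RNG seed for the noise draws.
#' @return A `surrogate_spec` object.
#' @export
surrogate_spec <- function(latency = 0, amp_scale = 1, noise_sd = 0,
                           artifact_heights = NULL, artifact_width = 0.3,
                           contamination_gain = 0, seed = NULL) {
  if (artifact_width <= 0) stop("`artifact_width` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(latency = latency, amp_scale = amp_scale, noise_sd = noise_sd,
                 artifact_heights = artifact_heights,
                 artifact_width = artifact_width,
                 contamination_gain = contamination_gain, seed = seed),
            class = "surrogate_spec")
}

#' @rdname surrogate_spec
#' @param ... overrides passed on to [surrogate_spec()].
#' @export
surface_espec <- function(...) {
  defaults <- list(amp_scale = 0.9356, contamination_gain = 1,
                   artifact_heights = "auto", artifact_width = 0.3,
                   noise_sd = 0, latency = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(surrogate_spec, args)
}

# Shared estimator for the "breathing maximum immediately preceding" a couch
# step: the maximum above the local mid-level, i.e. half the peak-to-peak
# range of the curve over the beam-on segment just before `onset` (invariant
# to the baseline drift accumulated so far). Used both by the emulator (to
# size auto spike heights) and by the artifact detector (to derive the
# scaling factor), so that the two agree on identical samples.
preceding_breathing_max <- function(t, amp, events, onset) {
  iv <- events$intervals
  dt <- stats::median(diff(t))
  # tolerate grid-snapped vs analytic edges differing by up to one sample
  prev <- which(iv[, 2] <= onset + dt + 1e-9)
  if (length(prev) == 0)
    stop("no X-ray-on segment precedes the couch step at t = ", onset,
         call. = FALSE)
  k <- prev[length(prev)]
  sel <- t >= iv[k, 1] & t < iv[k, 2]
  if (sum(sel) < 3)
    stop("preceding X-ray-on segment contains too few samples", call. = FALSE)
  (max(amp[sel]) - min(amp[sel])) / 2
}

#' Emulate a surrogate recording of a ground-truth curve
#'
#' Applies the measurement-chain model of a [surrogate_spec()] to a
#' ground-truth curve: gain, latency (linear interpolation on the fixed
#' grid), Gaussian noise, and — when a table profile with couch steps is
#' given and `contamination_gain != 0` or artifact heights are set — the
#' sequence-scanning contamination: after the k-th couch step onset the
#' baseline drops by `contamination_gain * step`, and the samples inside
#' the artifact window `[onset, onset + artifact_width]` are replaced by a
#' linear bridge plus a triangular peak of the configured height.
#'
#' An all-default (identity) spec returns the input samples unchanged. The
#' X-ray status channel is copied from the truth curve unshifted: the
#' scanner's events are the fixed time frame.
#'
#' @param truth a [breathing_curve()] (ground truth).
#' @param table a `table_profile` covering the curve's time span, or `NULL`
#'   for a static couch.
#' @param espec a [surrogate_spec()].
#' @param system_label label for the emulated recording.
#' @return A [breathing_curve()].
#' @export
emulate_surrogate <- function(truth, table = NULL, espec = surrogate_spec(),
                              system_label = "emulated") {
  stopifnot(inherits(truth, "breathing_curve"), inherits(espec, "surrogate_spec"))
  t <- truth$t
  if (!is.null(table)) {
    if (min(table$t) > min(t) + 1e-9 || max(table$t) < max(t) - 1e-9)
      stop("table profile does not cover the curve's time span", call. = FALSE)
  }
  amp <- if (espec$latency != 0)
    espec$amp_scale * interp_lin(t, truth$amp, t - espec$latency)
  else espec$amp_scale * truth$amp
  if (espec$noise_sd > 0)
    amp <- amp + with_seed(espec$seed %||% 0L,
                           stats::rnorm(length(t), 0, espec$noise_sd))
  want_artifacts <- !is.null(table) &&
    (espec$contamination_gain != 0 || !is.null(espec$artifact_heights))
  if (want_artifacts) {
    onsets <- table$move_onsets
    deltas <- table$step_deltas
    heights <- espec$artifact_heights
    auto <- identical(heights, "auto")
    if (!auto && !is.null(heights) && length(heights) != length(onsets))
      stop("`artifact_heights` must have one entry per table step",
           call. = FALSE)
    events <- if (any(truth$xray_on)) xray_events(truth) else NULL
    dt <- curve_dt(truth)
    w <- espec$artifact_width
    for (k in seq_along(onsets)) {
      o <- onsets[k]
      if (o < min(t) || o + w > max(t))
        stop("couch step ", k, " lies outside the curve's time span",
             call. = FALSE)
      # amplitude scale drift: baseline drops as the patch travels deeper
      amp[t >= o - 1e-9] <- amp[t >= o - 1e-9] -
        espec$contamination_gain * deltas[k]
      h <- if (auto) {
        if (is.null(events))
          stop("auto artifact heights need X-ray-on status on the truth curve",
               call. = FALSE)
        espec$contamination_gain *
          preceding_breathing_max(t, amp, events, o)
      } else if (is.null(heights)) 0 else heights[k]
      if (h != 0) {
        inside <- which(t >= o - 1e-9 & t <= o + w + 1e-9)
        pre <- min(inside) - 1L
        post <- max(inside) + 1L
        if (pre < 1 || post > length(t))
          stop("artifact window at couch step ", k,
               " extends beyond the curve", call. = FALSE)
        bridge <- interp_lin(c(t[pre], t[post]), c(amp[pre], amp[post]), t[inside])
        apex_t <- o + w / 2
        tri <- h * pmax(0, 1 - abs(t[inside] - apex_t) / (w / 2))
        # make sure the apex height is realized exactly on-grid
        apex_i <- which.min(abs(t[inside] - apex_t))
        tri[apex_i] <- h
        amp[inside] <- bridge + tri
      }
    }
  }
  breathing_curve(t, amp, xray_on = truth$xray_on, system_label = system_label)
}

#' Phantom geometry specification
#'
#' Geometry of the rendered dynamic thorax phantom: an isotropic voxel cube
#' containing a homogeneous spherical tumor in lung-like background. The
#' third array dimension is the inferior-superior axis along which the
#' tumor moves; coordinates are in mm relative to the grid centre.
#'
#' @param grid_n cube edge length in voxels.
#' @param voxel_size isotropic voxel size, mm.
#' @param tumor_radius sphere radius, mm.
#' @param tumor_hu,background_hu attenuation values in Hounsfield units;
#'   the segmentation threshold must lie strictly between them.
#' @param threshold_hu default HU threshold used for segmentation.
#' @return A `phantom_geometry` object.
#' @export
phantom_geometry <- function(grid_n = 64, voxel_size = 1, tumor_radius = 10,
                             tumor_hu = 50, background_hu = -800,
                             threshold_hu = -200) {
  if (tumor_hu <= threshold_hu || threshold_hu <= background_hu)
    stop("need tumor_hu > threshold_hu > background_hu", call. = FALSE)
  structure(list(grid_n = as.integer(grid_n), voxel_size = voxel_size,
                 tumor_radius = tumor_radius, tumor_hu = tumor_hu,
                 background_hu = background_hu, threshold_hu = threshold_hu),
            class = "phantom_geometry")
}

voxel_coords <- function(geometry) {
  n <- geometry$grid_n
  (seq_len(n) - (n + 1) / 2) * geometry$voxel_size
}

#' Render a series of tumor phantom volumes
#'
#' One voxel volume per tumor position: a voxel takes `tumor_hu` when its
#' centre lies within `tumor_radius` of the sphere centre (displaced along
#' the inferior-superior axis), else `background_hu`. Positions that would
#' clip the sphere at the grid boundary are rejected.
#'
#' @param positions numeric vector of inferior-superior tumor centre
#'   offsets, mm.
#' @param geometry a [phantom_geometry()].
#' @param bin_labels optional labels, one per position.
#' @return A `phantom_series`: list with `volumes` (list of 3-D arrays),
#'   `geometry`, `bin_labels`, `true_positions`.
#' @export
render_phantom_series <- function(positions, geometry = phantom_geometry(),
                                  bin_labels = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  half <- geometry$grid_n * geometry$voxel_size / 2
  if (any(abs(positions) + geometry$tumor_radius > half))
    stop("tumor sphere would be clipped at the grid boundary for |position| = ",
         max(abs(positions)), " mm", call. = FALSE)
  if (is.null(bin_labels)) bin_labels <- sprintf("pos%02d", seq_along(positions))
  if (length(bin_labels) != length(positions))
    stop("`bin_labels` must match `positions` in length", call. = FALSE)
  cc <- voxel_coords(geometry)
  n <- geometry$grid_n
  r2xy <- outer(cc^2, cc^2, `+`)  # x^2 + y^2 slab, reused per position
  volumes <- lapply(positions, function(p) {
    dz2 <- (cc - p)^2
    vol <- array(geometry$background_hu, dim = c(n, n, n))
    for (k in seq_len(n)) {
      inside <- r2xy <= geometry$tumor_radius^2 - dz2[k]
      if (any(inside)) {
        slab <- vol[, , k]
        slab[inside] <- geometry$tumor_hu
        vol[, , k] <- slab
      }
    }
    vol
  })
  structure(list(volumes = volumes, geometry = geometry,
                 bin_labels = bin_labels, true_positions = positions),
            class = "phantom_series")
}

#' @export
print.phantom_series <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<phantom_series> %d volume(s), %d^3 voxels at %g mm, tumor r = %g mm\n",
              length(x$volumes), g$grid_n, g$voxel_size, g$tumor_radius))
  cat(sprintf("  positions (mm): %s\n",
              paste(round(x$true_positions, 2), collapse = ", ")))
  invisible(x)
}

#' Inferior-superior centre of mass of the segmented tumor
#'
#' Segments a volume by HU thresholding (voxels `>= threshold`) and returns
#' the binary-mask centre of mass along the inferior-superior axis, in mm
#' relative to the grid centre.
#'
#' @param volume a 3-D HU array (as produced by [render_phantom_series()]).
#' @param geometry the matching [phantom_geometry()].
#' @param threshold_hu segmentation threshold; defaults to the geometry's.
#' @return centre of mass in mm.
#' @export
com_is <- function(volume, geometry, threshold_hu = geometry$threshold_hu) {
  mask_per_slice <- apply(volume >= threshold_hu, 3, sum)
  if (sum(mask_per_slice) == 0)
    stop("empty segmentation: no voxel reaches the HU threshold", call. = FALSE)
  z <- voxel_coords(geometry)
  sum(z * mask_per_slice) / sum(mask_per_slice)
}

#' Write a phantom series to NIfTI files
#'
#' One NIfTI-1 file per bin plus a JSON sidecar recording voxel size,
#' labels and true tumor positions.
#'
#' @param series a `phantom_series`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the sidecar path.
#' @export
write_phantom_series <- function(series, dir) {
  stopifnot(inherits(series, "phantom_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vs <- series$geometry$voxel_size
  files <- character(length(series$volumes))
  for (i in seq_along(series$volumes)) {
    files[i] <- file.path(dir, paste0(make.names(series$bin_labels[i]), ".nii.gz"))
    img <- RNifti::asNifti(series$volumes[[i]], pixdim = c(vs, vs, vs))
    RNifti::writeNifti(img, files[i])
  }
  sidecar <- file.path(dir, "phantom_series.json")
  jsonlite::write_json(
    list(voxel_size_mm = vs, bin_labels = series$bin_labels,
         true_positions_mm = series$true_positions,
         tumor_radius_mm = series$geometry$tumor_radius,
         tumor_hu = series$geometry$tumor_hu,
         background_hu = series$geometry$background_hu,
         files = basename(files)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
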
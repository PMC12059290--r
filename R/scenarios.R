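#' Simulate a complete surface-camera sequence-scan recording
#'
#' End-to-end study builder for the table-motion-correction workflow:
#' generates a ground-truth breathing curve, lays out `n_steps + 1`
#' beam-on segments separated by couch moves (each segment slightly longer
#' than one breathing cycle, a 20 s training period before the first
#' X-ray-on), builds the matching couch profile with the fixed table
#' increment, and emulates the surface-camera recording with its
#' patch-propagation artifacts and amplitude scale drift.
#'
#' @param Ap2p,rate,waveform,grid_dt passed to [curve_spec()].
#' @param n_steps number of couch increments (segments = `n_steps + 1`).
#' @param espec a [surrogate_spec()]; the surface preset by default.
#' @param first_on start of irradiation, s (20 s training before it).
#' @param move_duration couch move time, s.
#' @param gap_pad extra beam-off time after each move, s.
#' @param step_size couch increment, mm.
#' @param seed RNG seed forwarded to the curve spec.
#' @param amp_jitter,rate_jitter forwarded to [curve_spec()].
#' @return A list: `truth` (with X-ray status), `emulated`, `events`,
#'   `profile`, `espec`, `spec`.
#' @export
#' @examples
#' st <- simulate_surface_study(Ap2p = 10, rate = 12, n_steps = 2)
#' res <- correct_surface_curve(st$emulated, st$profile, st$events)
#' compare_maxima(res$curve, st$truth)$mean_pct
simulate_surface_study <- function(Ap2p = 10, rate = 12, n_steps = 3,
                                   espec = surface_espec(),
                                   waveform = "sin", first_on = 20,
                                   move_duration = 1, gap_pad = 0.5,
                                   step_size = 34.5, grid_dt = 0.020,
                                   seed = NULL, amp_jitter = 0,
                                   rate_jitter = 0) {
  Tcycle <- 60 / rate
  snap <- function(x) round(x / grid_dt) * grid_dt
  seg <- snap(Tcycle + 1)
  gap <- snap(move_duration + gap_pad)
  n_segments <- n_steps + 1L
  duration <- snap(first_on + n_segments * seg + n_steps * gap + 2 * Tcycle)
  spec <- curve_spec(waveform, Ap2p = Ap2p, rate = rate, duration = duration,
                     grid_dt = grid_dt, amp_jitter = amp_jitter,
                     rate_jitter = rate_jitter, seed = seed)
  truth <- generate_curve(spec)
  on <- snap(first_on + (seq_len(n_segments) - 1) * (seg + gap))
  ev <- xray_events(on, on + seg, source = "simulated")
  truth <- apply_xray_events(truth, ev)
  events <- xray_events(truth)  # grid-exact edges from the status channel
  profile <- table_profile_from_events(events, span = range(truth$t),
                                       n_steps = n_steps,
                                       move_duration = move_duration,
                                       step_size = step_size,
                                       grid_dt = grid_dt)
  emulated <- emulate_surrogate(truth, profile, espec,
                                system_label = "surface")
  list(truth = truth, emulated = emulated, events = events,
       profile = profile, espec = espec, spec = spec)
}

#' Simulate a breathing-adapted acquisition with intelligent triggering
#'
#' Study builder for the trigger/binning/latency analyses: generates a
#' ground-truth curve, runs the 20 s training analysis, simulates the
#' X-ray on/off trigger state machine for `n_segments` couch positions and
#' stamps the resulting events onto the curve.
#'
#' @inheritParams simulate_surface_study
#' @param n_segments number of beam-on segments.
#' @param training_s training window length, s.
#' @return A list: `curve` (with simulated X-ray status), `params`
#'   ([analyze_training()] output), `events`, `spec`.
#' @export
simulate_i4dct_study <- function(Ap2p = 10, rate = 12, n_segments = 4,
                                 waveform = "sin", training_s = 20,
                                 move_duration = 1, grid_dt = 0.020,
                                 seed = NULL, amp_jitter = 0,
                                 rate_jitter = 0) {
  Tcycle <- 60 / rate
  duration <- training_s + 2 + n_segments * (2.5 * Tcycle + move_duration + 2)
  spec <- curve_spec(waveform, Ap2p = Ap2p, rate = rate, duration = duration,
                     grid_dt = grid_dt, amp_jitter = amp_jitter,
                     rate_jitter = rate_jitter, seed = seed)
  curve <- generate_curve(spec)
  params <- analyze_training(curve, first_on = training_s,
                             window_s = training_s)
  events <- simulate_triggers(curve, params, n_segments,
                              move_duration = move_duration)
  curve <- apply_xray_events(curve, events)
  list(curve = curve, params = params, events = events, spec = spec)
}
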
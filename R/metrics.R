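#' Segment a breathing curve into cycles
#'
#' Inhalation peaks and exhalation valleys are identified with a
#' turning-point detector: local extrema whose swing exceeds
#' `min_prom_frac` of the global amplitude range, resolved to alternate
#' strictly in time (plateaus resolve to their centre sample). Extremum
#' times and values are refined to sub-sample precision by a local
#' quadratic fit. Each valley pair delimits one complete cycle; partial
#' cycles at the record boundaries are discarded.
#'
#' @param curve a [breathing_curve()].
#' @param min_prom_frac minimum extremum swing as a fraction of the global
#'   amplitude range (default 0.2).
#' @return A `cycle_set`: list with `valleys`, `peaks` (data.frames with
#'   `time`, `value`) and `cycles` (data.frame with `start`, `peak`, `end`
#'   times, `bpm` = 60/(end-start), `amp` = peak value minus the mean of
#'   the flanking valley values).
#' @export
#' @examples
#' bc <- generate_curve(curve_spec("sin", 10, 12, 60))
#' cs <- detect_cycles(bc)
#' nrow(cs$cycles)
detect_cycles <- function(curve, min_prom_frac = 0.2) {
  stopifnot(inherits(curve, "breathing_curve"))
  rng <- diff(range(curve$amp))
  if (rng <= 0) stop("constant signal: no breathing cycles", call. = FALSE)
  ext <- significant_extrema(curve$amp, min_prom_frac * rng)
  if (sum(ext$type == "valley") < 2)
    stop("fewer than 2 valleys detected; cannot segment cycles", call. = FALSE)
  refined <- t(vapply(ext$index, function(i)
    refine_extremum(curve$t, curve$amp, i), numeric(2)))
  ext$time <- refined[, 1]
  ext$value <- refined[, 2]
  valleys <- ext[ext$type == "valley", c("time", "value")]
  peaks <- ext[ext$type == "peak", c("time", "value")]
  row.names(valleys) <- row.names(peaks) <- NULL
  cycles <- data.frame(start = numeric(0), peak = numeric(0), end = numeric(0),
                       bpm = numeric(0), amp = numeric(0))
  for (j in seq_len(nrow(valleys) - 1)) {
    v0 <- valleys$time[j]; v1 <- valleys$time[j + 1]
    pk <- which(peaks$time > v0 & peaks$time < v1)
    if (length(pk) != 1) next  # alternation guarantees at most one
    cycles <- rbind(cycles, data.frame(
      start = v0, peak = peaks$time[pk], end = v1,
      bpm = 60 / (v1 - v0),
      amp = peaks$value[pk] - mean(c(valleys$value[j], valleys$value[j + 1]))))
  }
  structure(list(valleys = valleys, peaks = peaks, cycles = cycles),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d complete cycle(s), %d peak(s), %d valley(s)\n",
              nrow(x$cycles), nrow(x$peaks), nrow(x$valleys)))
  if (nrow(x$cycles) > 0)
    cat(sprintf("  mean BR %.2f BPM, mean amp %.2f\n",
                mean(x$cycles$bpm), mean(x$cycles$amp)))
  invisible(x)
}

#' Breathing-rate and amplitude statistics
#'
#' Summary statistics over the per-cycle breathing rate (60 / valley-to-
#' valley interval, in breaths per minute) and per-cycle amplitude of a
#' [detect_cycles()] segmentation: the statistics reported per surrogate
#' system in curve-quality evaluations. `std_amp_pct` is the standard
#' deviation of the per-cycle amplitude expressed as a percentage of the
#' mean per-cycle amplitude.
#'
#' @param cycles a `cycle_set` with at least one complete cycle.
#' @return A `br_stats` object (named list): `max_bpm`, `min_bpm`,
#'   `mean_bpm`, `median_bpm`, `std_bpm`, `std_amp_pct`, `n_cycles`.
#' @export
br_stats <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  cy <- cycles$cycles
  if (nrow(cy) == 0) stop("empty cycle set", call. = FALSE)
  bpm <- cy$bpm
  amp <- cy$amp
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(
    max_bpm = max(bpm), min_bpm = min(bpm), mean_bpm = mean(bpm),
    median_bpm = stats::median(bpm), std_bpm = sd0(bpm),
    std_amp_pct = if (mean(amp) > 0) 100 * sd0(amp) / mean(amp) else NA_real_,
    n_cycles = nrow(cy)),
    class = "br_stats")
}

#' @export
print.br_stats <- function(x, ...) {
  cat(sprintf(paste0("<br_stats> %d cycle(s)\n",
                     "  BR (BPM): mean %.2f, median %.2f, min %.2f, max %.2f, STD %.2f\n",
                     "  AMP STD: %.2f %%\n"),
              x$n_cycles, x$mean_bpm, x$median_bpm, x$min_bpm, x$max_bpm,
              x$std_bpm, x$std_amp_pct))
  invisible(x)
}

#' Compare per-cycle amplitude maxima between two systems
#'
#' Matches each inhalation peak of the test curve to the nearest reference
#' peak within half a cycle period (ties toward the earlier peak) and
#' reports the percentage deviation
#' `(test_max - ref_max) / ref_max * 100` per matched pair, its mean and
#' standard deviation. Both curves must be in absolute units (mm).
#'
#' @param test,reference aligned, un-normalized [breathing_curve()]s.
#' @param min_prom_frac passed to [detect_cycles()].
#' @return A list: `mean_pct`, `sd_pct`, `n`, `per_cycle_pct`,
#'   `test_times`, `ref_times`.
#' @export
compare_maxima <- function(test, reference, min_prom_frac = 0.2) {
  if (test$units_normalized || reference$units_normalized)
    stop("compare_maxima needs absolute (un-normalized) amplitudes",
         call. = FALSE)
  cs_t <- detect_cycles(test, min_prom_frac)
  cs_r <- detect_cycles(reference, min_prom_frac)
  if (nrow(cs_t$peaks) == 0 || nrow(cs_r$peaks) == 0)
    stop("no peaks to match", call. = FALSE)
  Tcycle <- stats::median(diff(cs_r$valleys$time))
  window <- Tcycle / 2
  dev <- numeric(0); tt <- numeric(0); rt <- numeric(0)
  for (j in seq_len(nrow(cs_t$peaks))) {
    d <- abs(cs_r$peaks$time - cs_t$peaks$time[j])
    k <- which(d <= window + 1e-9)
    if (length(k) == 0) next
    k <- k[order(d[k], cs_r$peaks$time[k])][1]  # nearest, tie -> earlier
    dev <- c(dev, 100 * (cs_t$peaks$value[j] - cs_r$peaks$value[k]) /
               cs_r$peaks$value[k])
    tt <- c(tt, cs_t$peaks$time[j]); rt <- c(rt, cs_r$peaks$time[k])
  }
  if (length(dev) == 0) stop("no matched peaks within half a cycle", call. = FALSE)
  list(mean_pct = mean(dev),
       sd_pct = if (length(dev) > 1) stats::sd(dev) else 0,
       n = length(dev), per_cycle_pct = dev, test_times = tt, ref_times = rt)
}
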
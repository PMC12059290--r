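# resp4dct

Simulation and evaluation toolkit for respiratory surrogate signals in
intelligent, breathing-adapted four-dimensional CT (4DCT) sequence
scanning.

Breathing-adapted 4DCT triggers the X-ray beam prospectively from a
surrogate breathing signal: a 20 s training period before the first
X-ray-on is analyzed to pick scan parameters and to build a reference
breathing curve (RBC), the beam is switched on per couch position for one
valid breathing cycle plus the gantry rotation time, and ten amplitude- or
phase-based reconstruction bins are placed on the best-matching cycle of
each beam-on segment. Surrogate systems that are not mounted on the couch
(ceiling-mounted surface cameras, side-mounted optical trackers) see the
couch move by a fixed 34.5 mm increment between segments; a surface
camera's internal patch propagation then leaves narrow peak artifacts and
an amplitude scale drift in the breathing curve. This package provides the
whole desk-scale machinery to study that workflow without scanner access:

* **Synthetic ground truth** — sinusoidal curves
  ζ(t) = (A_p2p/2)·sin(2πt/T_cycle) and end-exhale-weighted
  ζ(t) = (A_p2p/2)·cos⁶(2πt/T_cycle), amplitudes 2–20 mm, rates
  6–20 BPM, with per-cycle amplitude/period jitter; couch staircase
  profiles; voxelized spherical-tumor phantoms for image-quality
  evaluation.
* **Surrogate emulation** — gain, latency, Gaussian noise, and the
  sequence-scanning contamination of non-couch-mounted systems
  (per-step baseline drop of `contamination_gain × 34.5 mm` plus a
  triangular peak artifact at each couch-step onset).
* **Table-motion correction** — detects the peak artifacts in the
  X-ray-off gaps, derives a per-step scaling factor as artifact height
  over the preceding breathing maximum, excises the spikes, and adds the
  scaled couch profile back cumulatively after each beam-on segment
  (`detect_artifacts()`, `strip_system_correction()`,
  `apply_table_correction()`, or the `correct_surface_curve()` wrapper);
  a two-tool reference tracker is handled by `subtract_reference_tool()`.
* **Curve processing** — CSV / vxp-like / tracker-log readers, 20 ms
  resampling, alignment by the first X-ray-on edge, normalization to the
  first post-irradiation minimum/maximum pair.
* **Breathing metrics** — valley-pair cycle segmentation with sub-sample
  extremum refinement, BR statistics (min/max/mean/median/STD in BPM,
  amplitude STD in %), per-cycle maxima comparison between systems.
* **Trigger / binning simulation** — training analysis
  (`analyze_training()`), a documented state-machine stand-in for the
  vendor's trigger logic (`simulate_triggers()`), bin placement
  (`plan_bins()`), and inferior–superior tumor centre-of-mass evaluation
  on the rendered phantom (`evaluate_com()`).
* **Latency analysis** — artificial shifts (−500…+500 ms), their
  centre-of-mass impact (`latency_sweep()`), and inter-system latency
  estimation from smoothed, parabola-refined maxima
  (`estimate_latency()`).

## Worked example

Emulate a surface-camera recording of a 10 mm, 12 BPM sine over four
beam-on segments with three 34.5 mm couch steps, correct it, and compare
it with the ground truth:

```r
library(resp4dct)

st  <- simulate_surface_study(Ap2p = 10, rate = 12, n_steps = 3, seed = 1)
res <- correct_surface_curve(st$emulated, st$profile, st$events)
res$artifacts[[1]]
#> <artifact_event> after segment 1: onset 26.00 s, height 4.68 mm, scale 1.000

cm <- compare_maxima(res$curve, st$truth)
sprintf("maxima deviation: %.2f +/- %.2f %% over %d cycles",
        cm$mean_pct, cm$sd_pct, cm$n)
#> "maxima deviation: -6.50 +/- 0.14 % over 12 cycles"

br_stats(detect_cycles(res$curve))
#> <br_stats> 10 cycle(s)
#>   BR (BPM): mean 12.00, median 12.00, min 11.83, max 12.17, STD 0.08
#>   AMP STD: 0.08 %
```

The detected scaling factor (1.000) recovers the emulated contamination
gain exactly; the residual −6.50 % maxima deviation is the emulated
surface-camera gain (0.9356, i.e. −6.4 %, the bridged artifact windows
account for the rest), well inside the 10 % amplitude and 1 % breathing-
rate bounds the correction is designed to meet. Latency between two
recordings is estimated to sub-grid precision:

```r
estimate_latency(shift_curve(st$truth, 45), st$truth)
#> <latency_estimate> -45.0 +/- 0.0 ms over 8 maxima
```

(negative lag: the second curve leads the first by 45 ms).

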
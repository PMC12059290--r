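---
title: "Simulating breathing surrogates for breathing-adapted 4DCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating breathing surrogates for breathing-adapted 4DCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resp4dct)
```

## Scope and model overview

Breathing-adapted 4DCT sequence scanning couples a prospective X-ray
trigger to an external breathing surrogate. The acquisition alternates
beam-on segments at fixed couch positions with discrete couch increments
(34.5 mm here), analyzes a 20 s training period before the first
X-ray-on, and retrospectively sorts projections into ten amplitude- or
ten phase-based bins guided by a reference breathing curve (RBC). This
package reproduces that workflow at the *breathing-curve level*: no
projections or reconstructions are simulated; image quality is proxied by
the inferior–superior centre of mass (COM) of a spherical tumor rendered
into a voxel phantom at the positions the binning selects. Everything a
scanner would provide is emulated, so every stage is testable on a desk.

The vendor's real trigger logic applies phase-space constraints that are
not public; `simulate_triggers()` replaces them with a documented state
machine (arm at an exhalation valley; beam on for one *valid* complete
cycle plus the gantry rotation time; invalid cycles extend the segment;
couch move during beam-off). This is the package's central and deliberate
simplification. Likewise the automatic parameter selection is represented
by one documented rule: the gantry rotation time is the largest value of
`{0.25, 0.35, 0.5, 1.0}` s not exceeding a quarter of the mean training
cycle.

## Synthetic breathing curves

Two waveform families are generated on a uniform grid (default 20 ms, the
common export resolution of gating systems):

* `sin`: ζ(t) = (A_p2p/2)·sin(2πt/T_cycle),
* `cos6`: ζ(t) = (A_p2p/2)·cos⁶(2πt/T_cycle),

with `T_cycle = 60/rate`. The design space is A_p2p ∈ [2, 20] mm and
rate ∈ [6, 20] BPM; values outside it warn but are accepted. The `cos6`
form is implemented literally as written above; note that cos⁶ of a
2π-periodic argument repeats every *half* period, so the apparent cycle
rate of a `cos6` curve is twice the nominal `rate`. Its long
near-zero valleys represent the end-exhale dwell; the curve rides from 0
(exhale plateau) up to A_p2p/2.

Irregularity is modelled per cycle: cycle *k* draws a multiplicative
period factor ~ N(1, `rate_jitter`) and amplitude factor
~ N(1, `amp_jitter`), both truncated at ±3σ (preventing negative
periods). The phase advances continuously across cycle boundaries, and
the amplitude envelope is interpolated linearly between cycle midpoints,
so jittered curves have no jumps. One named seed controls all draws.

## Surrogate emulation

`emulate_surrogate()` applies a measurement-chain model:

```
s(t) = amp_scale · ζ(t − latency) + noise + table contamination
```

For non-couch-mounted systems during sequence scanning, the contamination
has two parts, both anchored at the couch-step onsets (which coincide
with the X-ray-off edges):

1. *Amplitude scale drift*: after step *k* the baseline drops by
   `contamination_gain × step_size`, emulating the measured amplitude
   decaying as the tracked patch travels deeper into the gantry.
2. *Peak artifact*: during the move the system's patch propagation loses
   the breathing signal; the samples inside the artifact window (default
   0.3 s) are replaced by a linear bridge plus a triangular peak. With
   `artifact_heights = "auto"` the apex height is
   `contamination_gain ×` the preceding breathing maximum, so the
   artifact itself encodes the system's scaling.

The "preceding breathing maximum" is defined as half the peak-to-peak
range over the beam-on segment immediately before the step — a baseline-
drift-invariant quantity that equals the usual "maximum above baseline"
for zero-centred signals. Emulator and detector share this estimator
verbatim, so on clean signals the detected scaling factor equals the
emulated contamination gain exactly.

The surface-camera preset `surface_espec()` uses `amp_scale = 0.9356`
(the ≈ −6.4 % maxima underestimate observed for corrected surface-camera
curves in reference phantom measurements), `contamination_gain = 1`, auto
artifact heights, and `noise_sd = 0`. The zero noise default is a
deliberate study condition: the correction multiplies the derived scaling
factor by the full 34.5 mm couch profile, so an error δh on the measured
artifact height propagates as `n_steps · 34.5 mm · δh / M` into the
corrected baseline (M = preceding maximum). At A_p2p = 2 mm even 0.05 mm
of sensor noise would exceed the 10 % amplitude budget — a sensitivity of
the correction method itself, not of this implementation. Noise remains a
parameter and is exercised separately in the tests.

## Table-motion correction

The retrospective fix for surface-camera curves proceeds in three steps,
mirroring how the artifacts arise:

1. `detect_artifacts()` inspects each X-ray-off gap, anchored at the off
   edge (patch propagation is triggered by the end of acquisition at a
   couch position). An artifact is accepted when its excursion above the
   local linear bridge exceeds 0.25 × the preceding breathing maximum
   *and* its slope exceeds 1.5 × the maximum physiological slope observed
   in the training region. The slope factor is deliberately modest: the
   spike's slope (2h/w) is independent of the breathing period while the
   physiological bound scales with 1/T_cycle, so a large factor would
   miss artifacts at fast breathing rates. The scaling factor is artifact
   height over the preceding breathing maximum.
2. `strip_system_correction()` excises each artifact window with a linear
   bridge, rejoining the local baseline.
3. `apply_table_correction()` adds the independently measured couch
   profile, multiplied by each step's scaling factor, cumulatively from
   the end of the corresponding beam-on segment onward, cancelling the
   accumulated drift; the artifact windows are re-bridged afterwards.
   Samples before the first X-ray-off are never modified.

Because the forward model and the correction are exact inverses up to the
bridged windows, a corrected emulated curve recovers the ground truth to
within the emulated gain: across the full design grid (A_p2p ∈ {2, 10,
20} mm × rate ∈ {6, 12, 20} BPM, three couch steps) the per-cycle maxima
deviate by at most ≈ 6.8 % (the preset gain accounts for 6.44 points of
that) and the mean breathing rate by < 0.01 %.

A side-mounted reference tracker avoids the problem altogether by
tracking a second tool on the couch; `subtract_reference_tool()` removes
the couch channel sample-wise.

## Cycle segmentation and curve statistics

`detect_cycles()` finds alternating peaks/valleys by turning-point
simplification: extrema whose swing is below 20 % of the global range are
merged away, plateaus resolve to their centre sample, and each surviving
extremum is refined to sub-sample precision by a local quadratic fit.
Each valley pair is one complete cycle (partials at the record edges are
discarded); the per-cycle rate is 60/(valley-to-valley interval) in BPM
and the per-cycle amplitude is the peak minus the mean of its flanking
valleys. `br_stats()` summarizes min/max/mean/median/STD of the rate and
the amplitude STD as a percentage of the mean per-cycle amplitude (the
denominator is a package convention; only relative comparisons use it).
On a jitter-free sinusoid these statistics are exact: a 100 s, 12 BPM,
10 mm curve yields mean BR 12.00 BPM with STD ~0 (numerically ≲ 1e-4).

`compare_maxima()` matches inhalation peaks nearest-in-time within half a
cycle (ties toward the earlier peak) and reports per-cycle percentage
deviations of the maxima; amplitude comparisons require un-normalized
curves.

## Training, RBC and binning conventions

`analyze_training()` requires the 20 s window before the first X-ray-on
to contain at least three complete cycles. The RBC is the mean of the
training cycles resampled to 101 phase samples from one inhalation
maximum to the next, so phase 0 % is the start of exhalation and the
minimum lies strictly inside the cycle. Cycle validity for triggering
uses an amplitude band of 0.7–1.3 × the training mean and a ±30 % period
tolerance.

`plan_bins()` selects, per beam-on segment, the complete valley-to-valley
cycle with minimal RMS distance to the RBC (both normalized to the unit
range; the RBC is rotated to valley-start form for the comparison).
Amplitude bins are placed where the rising branch first crosses
0/20/40/60/80 % (Inh0–Inh80) and the falling branch 100/80/60/40/20 %
(Exh100–Exh20) of the branch's amplitude range, with linear interpolation
between samples; levels are taken per branch so that every crossing
exists even when the flanking valleys differ. Phase bins sit at tenths of
the cycle duration measured from the inhalation maximum; timestamps past
the covered cycle end wrap back by one period, keeping all ten timestamps
inside the covered cycle. When a strongly time-shifted curve leaves no
fully covered cycle inside a fixed beam-on interval (the ±500 ms entries
of the latency sweep), the best cycle overlapping by at least 70 % is
used and flagged as partial rather than failing the sweep.

`evaluate_com()` takes the binning timestamps, reads the *ground-truth*
tumor motion at those times (averaged over segments) — reconstructing the
same physical tumor with exchanged sorting curves, as a retrospective
curve swap would — renders a sphere per bin, segments by HU threshold and
computes the binary-mask COM along the inferior–superior axis. Amplitude
trajectories are normalized (anchored) to maximum inspiration; phase
trajectories to maximum expiration and inverted in amplitude.

## Phantom rendering

The default phantom is a 64³ grid of 1 mm isotropic voxels with a 10 mm
radius sphere of 50 HU in −800 HU background and a −200 HU segmentation
threshold (thresholding is the documented segmentation method; the HU
values themselves are package conventions chosen to be lung-like with a
comfortable margin on either side of the threshold). Motion spanning
±10 mm leaves ≥ 10 mm of margin to the grid boundary; positions that
would clip the sphere are rejected. Binary-mask COM errors against the
analytic sphere position stay well below half a voxel. Volumes can be
exported as NIfTI-1 with a JSON sidecar (`write_phantom_series()`).

## Latency machinery

`shift_curve()` delays (positive ms) or advances (negative ms) the
amplitude channel by linear interpolation on the fixed grid; the X-ray
status stays in the scanner's frame. `latency_sweep()` re-plans bins for
each shifted curve against fixed beam events and reports mean/STD of the
per-bin COM deviation from the unshifted trajectory; the 0 ms entry is
identically zero by construction, and on sinusoidal motion the deviation
STD grows monotonically with |shift| over the ±100 ms range, with the
±500 ms shifts dominating — the qualitative pattern expected of
latency-corrupted binning. Because the trajectories in this package come
from the synthetic phantom renderer rather than real reconstructions,
the nonzero cells are analogs, not reproductions; only the definitional
zero row is quantitative.

`estimate_latency()` smooths both curves with a 100 ms moving average,
refines each maximum after the first X-ray-on by a quadratic fit over
±250 ms, matches maxima nearest-in-time and averages the differences.
The sign convention is `lag = mean(t_max(b) − t_max(a))`: negative lag
means the second curve leads. Defaults were chosen so a 20 ms grid gives
sub-5 ms vertex resolution on ~5 s cycles; injected shifts from −500 to
+500 ms on noiseless sines are recovered within 5 ms, and the estimator
agrees with a brute-force cross-correlation oracle within one grid step.

## Numerical choices and degenerate inputs

* Extremum ties (two equal samples at a discrete extremum) resolve to the
  earlier sample before quadratic refinement; refinement offsets are
  clamped to one grid step.
* Amplitude-bin crossing levels pin the 0 %/100 % levels to the exact
  branch extrema to avoid one-ulp misses.
* Event edges may be analytic (from the trigger simulation) or snapped to
  the sample grid (from a status channel); all associations between couch
  steps, artifacts and beam segments tolerate one grid step of skew.
* Constant signals, windows with fewer than three training cycles,
  missing X-ray edges, overlapping artifact windows, couch steps without
  a scaling factor, and empty segmentations are all explicit errors.

## Problem sizes

The shipped tests and the acceptance script run the full pipelines at
their natural desk scale: 60–120 s curves on the 20 ms grid, 3–4 beam-on
segments, 64³ phantom volumes, 13-point latency sweeps and a 9-point
amplitude × rate design grid; the complete suite finishes in well under a
minute.

## Known limitations

* The trigger state machine and the rotation-time rule are documented
  surrogates for proprietary vendor logic; absolute trigger times should
  not be compared against a real scanner.
* No CT physics: no projections, scatter, partial-volume or
  reconstruction artifacts; COM on rendered spheres is an idealized
  image-quality proxy, so passing tests demonstrate the signal-processing
  chain, not clinical image quality.
* Tumor motion is single-axis (inferior–superior) and the surrogate and
  tumor amplitudes are coupled 1:1 unless the user supplies separate
  curves; real surrogate–tumor correspondence is looser.
* The table-motion correction inherits the method's intrinsic noise
  sensitivity (see above): with realistic sensor noise and small
  breathing amplitudes the scaled couch profile amplifies height-
  estimation errors beyond the 10 % amplitude budget.
* The contamination model uses a single scalar gain; real projection
  geometry (camera angle, patch position on a curved surface) is not
  modelled.
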
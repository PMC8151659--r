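---
title: "Spatiotemporal gait analysis from VR foot trackers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal gait analysis from VR foot trackers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrgait)
```

## The measurement problem

Consumer VR trackers (Lighthouse laser-sweep positioning) report world-frame
position and orientation of anything they are strapped to, at ~90 Hz, with
sub-centimeter accuracy. Mounted on the instep of each shoe, they give direct
foot displacement — no integration of accelerations, no drift — which makes
them a low-cost candidate for indoor gait analysis. `vrgait` turns a pair of
such pose streams into the standard spatiotemporal gait parameters, and
provides the statistical machinery to validate the whole chain against a
reference event source such as a pressure-sensing instrumented walkway.

The pipeline is: zero-phase low-pass filtering of the tracker trajectories →
rigid sensor-to-heel transformation → linear detrend of the vertical channel →
toe-off (TO) / heel-strike (HS) detection from the double-peaked vertical
clearance waveform → gait-cycle segmentation (with optional walkway
bounding-box gating of turnarounds) → per-stride features → validation
statistics.

## Trajectory conditioning

**Filter.** A third-order low-pass Butterworth with a 12 Hz cutoff, applied
forward and backward (`lowpass_zero_phase()`). Voluntary gait has essentially
all its energy below ~10 Hz, so 12 Hz passes the signal and rejects tracking
jitter. The forward-backward pass cancels the filter's phase delay — essential
here, because event *times* are the measurand and a causal filter would bias
every event late. The effective magnitude response is the squared single-pass
response: unity at DC, exactly 1/2 at the cutoff. Edges are handled by
odd-reflection padding of `3 * (order + 1)` samples with steady-state initial
conditions, so a constant signal is reproduced to machine precision and edge
transients do not leak into the first strides. The pass is implemented in the
package (padding + companion-form initial conditions around coefficients from
`signal::butter`), because a plain forward-backward application without
padding leaves large edge transients.

**Detrend.** The vertical channel is linearly detrended
(`detrend_linear()`) over the whole contiguous recording. VR world
calibration can leave the floor at a nonzero, slightly tilted height; the
detrend removes offset and tilt so the stance plateau becomes a flat
baseline. The horizontal axes are *not* detrended — stride length lives in
the X displacement, and detrending X would destroy it. The whole-recording
window is a deliberate choice; a per-lap detrend would track slow
calibration drift better but needs lap boundaries, which are themselves a
product of event detection.

**Resampling.** Streams recorded at another rate are brought to the analysis
rate by linear interpolation for waveforms (`resample_tracker()`, quaternions
renormalized after componentwise interpolation) and by nearest-grid snapping
for event tables (`snap_event_times()`): a reference device contributes
events, not waveforms, so snapping its timestamps onto the 90 Hz grid is the
faithful operation.

## Sensor-to-heel transformation

Gait features are conventionally defined at the heel, while the tracker sits
on the instep. `heel_position()` computes `heel = pos + R(q) · offset` with
`q` the world-from-tracker unit quaternion (scalar-first convention) and
`offset` the heel location in the tracker's local frame, taken from a
per-shoe-size table (`offset_for_shoe_size()`). Offsets must be measured
statically (e.g. with a camera system); the package ships only a clearly
labelled placeholder template and never invents anthropometric constants.
Two properties pin the convention down and are enforced by tests: the
heel-tracker distance equals `|offset|` at every sample, and the transform is
equivariant under global rigid motions.

## Event detection

After conditioning, each swing appears as a double-peaked excursion of the
vertical channel above the stance baseline: the first peak is the foot
lifting off (TO), the second the foot reaching the ground again (HS).
`detect_events()` implements this with three explicit parameters
(`detector_params()`):

* `min_prominence` (default **1 cm**) — foot clearance is multi-centimeter,
  so peaks with less than a centimeter of prominence are sensor jitter;
* `min_peak_separation_s` (default **100 ms**) — double peaks closer than
  100 ms cannot be the TO/HS pair of a human swing;
* `min_cycle_s` / `max_cycle_s` (defaults **0.4 s / 2.5 s**) — plausible
  stride durations; candidate cycles outside the bounds are dropped.

A *swing excursion* is a maximal run of samples higher than half
`min_prominence` above the stance floor. The floor is estimated as the lower
quartile of the signal rather than its median: the clearance excursion
legitimately occupies more than half of a cycle (heel rise precedes TO and
settling follows HS), which would pull the median off the floor, while the
foot is reliably flat for well over a quarter of the recording. An excursion
with exactly two qualifying peaks yields one TO and one HS at the peak
samples; any other count discards the excursion with a warning — a
conservative failure mode that loses a stride rather than fabricating an
event. Excursions touching the first or last sample are partial swings and
are discarded. Event time is the peak sample's time: no sub-sample
refinement and no onset back-tracking, so the detector stays simple,
deterministic, and honest about its one-sample resolution.

`segment_cycles()` then forms every consecutive HS→TO→HS triple into a gait
cycle. The first TO of a trial has no preceding HS, so N strides yield N − 1
cycles. `exclude_out_of_bounds()` keeps only cycles whose bounding heel
strikes fall inside the walkway rectangle (closed intervals), which removes
turnaround strides without any trajectory-curvature heuristics.

The detector is tailored to healthy, rhythmic gait. Pathological patterns
(shuffling, festination, drop foot) can fail the two-peaks-per-excursion
assumption and are out of scope.

## Stride features

For a cycle with events `HS(i−1)`, `TO(i)`, `HS(i)` and heel positions taken
at the event samples:

* **Stride length** `SL = ‖heel_XY(HS(i)) − heel_XY(HS(i−1))‖` (2D: the
  reference walkway only measures in its plane);
* **Stride time** `ST = t(HS(i)) − t(HS(i−1))`;
* **Stride width** `SW = sqrt(d² − (SL/2)²)`, with `d` the distance from the
  cycle-closing heel strike to the contralateral heel strike inside the
  cycle. This is the perpendicular heel-to-stride-line distance under the
  midpoint assumption of symmetric gait. When the geometry violates the
  assumption (`d < SL/2`) the radicand is negative; the stride is flagged
  invalid (`NaN`) rather than clamped to zero, so downstream statistics can
  exclude it explicitly. For left-foot strides the pairing is mirrored
  symmetrically.
* **Stride velocity** `SV = SL / ST`;
* **Stance / swing percentages** `STC% = 100·(t_TO − t_HS,prev)/ST`,
  `SWC% = 100 − STC%`. The two are complementary by construction; the suite
  verifies `STC% + SWC% = 100` to 1e-9 across a thousand randomized trials.

Heel positions at events are taken at the event's sample index without
interpolation — events are defined on samples, and mixing interpolated
positions with sample-resolution times would fake sub-sample accuracy.

## Validation statistics

`match_events()` pairs detected with reference events one-to-one, greedily by
ascending |Δt| within a tolerance window. The default window is **3 samples
at 90 Hz = 33.3 ms** (`match_tolerance()`): one-sample resolution is the
detector's floor, and three samples is the coarsest window that still
separates adjacent gait events. Greedy closest-first matching is determinate
and order-free; on gait-like streams, where inter-event gaps are an order of
magnitude larger than the window, it coincides with the exhaustive optimal
assignment (the suite checks this against a brute-force oracle on hundreds
of random instances). On adversarial inputs with several events packed
inside twice the tolerance, greedy matching can drop below the optimal
cardinality — a documented limitation that real event streams do not
exercise.

From the matches: **sensitivity** `= 100·TP/(TP+FN)`, where reference events
without a match are FN; detected events without a match are reported as FP
but do not enter sensitivity. Signed offsets (detected − reference) are
screened with a **3.5 × scaled-MAD** rule around the median
(`mad_outlier_mask()`, normal-consistency constant 1.4826, so the threshold
reads in SD-equivalents; with MAD = 0, any value off the median is an
outlier). Offset outliers — in practice tracking dropouts — are removed
before any statistics. The surviving offsets are summarized by mean ± SD,
mean absolute value ± SD, RMSE, and Bland–Altman **limits of agreement**
(mean ± 1.96·SD, the ~95% normal band). The identity
`RMSE² = mean² + (n−1)/n·SD²` is enforced as a property test.

`feature_agreement()` compares per-stride features between systems after
pairing strides by their matched closing heel strikes, reporting mean offset
± SD, mean absolute error ± SD, RMSE, Pearson r, and limits of agreement per
feature. When a feature has zero variance on either side (e.g. perfectly
periodic synthetic gait), the correlation is undefined and reported as `NA`
rather than coerced to 1. Reports present events in ms and features in cm,
ms, cm/s and % — the field's units — while all internal computation is SI.

If the two systems run on different clocks, the known offset between them
enters as `sync_offset_s` in the configuration and is subtracted from the
reference stream before matching; estimating the offset (hardware
synchronization) is out of scope.

## The synthetic gait simulator

`simulate_trial()` generates what the hardware pair would have produced, with
analytic ground truth. Per foot: heel strikes every `ST_true` seconds (feet
half a cycle apart), TOs at `HS + stance_fraction·ST`, heel X advancing
`SL_true` per stride along a half-cosine swing displacement (zero velocity at
every event — the foot lands and leaves smoothly), heel Y fixed at ± half
`SW_true`. The vertical channel is a per-swing clearance excursion: a low
pedestal with two raised-cosine bumps whose maxima sit *exactly* at the TO
and HS instants. Each bump is locally symmetric about its peak, so zero-phase
filtering does not displace the detected peak sample — a property the
first, asymmetric draft of the waveform failed, shifting detected events by
a sample. The saddle between the bumps stays above the detector's baseline
band so each swing is one excursion. Tracker pose is derived by inverting
the heel transformation under a constant yaw (exercising the quaternion
path), then corrupted with i.i.d. Gaussian position noise. The reference
stream is the truth events snapped to the reference grid (120 Hz by
default) and shifted by the configured clock offset.

Defaults are a comfortable adult walk: `SL = 1.25 m`, `ST = 1.1 s`,
`SW = 0.10 m`, 60% stance, clearance peaks 5 and 4 cm, tracker noise SD
3 mm. Each foot's first heel strike precedes its first clearance excursion
(the subject is already walking when recording starts), so truth and
reference streams begin at the first TO and N strides yield N − 1 cycles.

What the simulator deliberately does **not** model: stride-to-stride
physiological variability (every truth stride is identical, which is why
correlation against truth is reported `NA`), quaternion noise, tracking
dropouts beyond what position noise induces, gait asymmetry, turnarounds,
and soft-tissue / mounting artifacts. Passing the synthetic suite therefore
demonstrates the *algorithmic* correctness of the chain — grid-limited event
recovery, exact feature arithmetic, correct statistics — not the hardware
error budget of a real VR rig, which is dominated by mounting and
calibration effects the simulator cannot know.

## Numerical choices and degenerate inputs

* Filter edge handling: odd-reflection padding, steady-state initial
  conditions; signals shorter than the pad length are rejected with the
  minimum stated.
* Detector baseline: lower quartile of the conditioned signal; exact for the
  all-zero degenerate case.
* Tie-breaks in matching are resolved by reference order, making results
  independent of input permutation.
* `stride_width` invalid geometry → `NaN` + flag, never silent clamping.
* MAD = 0 branch: values off the median are outliers.
* Empty inputs return empty, typed results (no errors) everywhere a
  downstream stage can meaningfully continue; genuine contract violations
  (non-increasing time, non-unit quaternions, unknown event kinds) fail fast
  with located messages.

## Problem sizes in the test suite

The suite exercises 1,000 randomized 3-stride trials for the phase
conservation property, a 20-stride noiseless trial for grid-precision
recovery, a 200-stride 3 mm-noise trial for realistic error scales, 500
random instances against the brute-force matching oracle, and 100 random
geometries against the perpendicular-distance stride-width oracle; the whole
suite runs in about a minute.
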
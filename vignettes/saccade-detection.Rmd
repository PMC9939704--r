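---
title: "Deterministic saccade, fixation and blink detection from eye traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic saccade, fixation and blink detection from eye traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safide)
```

## The problem and the method

During free visual exploration the eye alternates between *fixations* —
slow drift within a small region, occupying 80–90% of the time — and
*saccades*, ballistic relocations lasting tens of milliseconds. Detecting
these events from a sampled eye trace is the first step of nearly every
gaze analysis, and when brain activity is time-locked to saccade or
fixation onset the detection must above all be *reproducible*: the same
trace must always yield the same events, with no hidden stochastic fitting
step, so that event rates and latencies are comparable between subjects,
sessions and laboratories.

`safide` implements such a fully deterministic detector. From one eye's
positions $(x_i, y_i)$ at times $t_i$ it computes

$$d_i = \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}, \qquad
  v_i = \frac{d_i}{t_{i+1}-t_i}, \qquad
  a_i = \frac{v_{i+1}-v_i}{t_{i+1}-t_i},$$

optionally converting $d_i$ to visual degrees with a pixels-per-degree
calibration constant. A sample interval is a *candidate* saccade interval
when $v_i \ge v_\mathrm{thr}$ **or** $a_i \ge a_+$ **or** $a_i \le a_-$
(inclusive comparisons), maximal runs of candidates are candidate
saccades, blinks are removed, implausibly small detections are filtered,
post-saccadic overshoots are folded back into their parent saccade, and
fixations are defined as everything that remains. No stage uses
randomness, smoothing, or iterative fitting.

The same pipeline handles three recording modalities:

* **video eye tracking** — positions in screen pixels, usually calibrated,
  with a pupil-size channel;
* **EOG** — positions from periocular electrodes (horizontal = right −
  left canthus, vertical = below − above the eye), in uncalibrated volts
  or arbitrary units, so all kinematics are *relative*;
* **scleral search coil** — voltages from a coil on the sclera; blinks are
  invisible here and blink detection is skipped.

## Threshold selection from the trace's own distributions

Velocity samples of a free-viewing trace form a long-tailed,
gamma-looking distribution: the bulk is fixational drift plus sensor
noise, the tail is saccadic. Since the eye fixates 80–90% of the time,
the boundary between bulk and tail sits near the corresponding upper
quantile. `suggest_thresholds()` therefore proposes

* $v_\mathrm{thr}$ = the velocity ECDF value at 85% accumulation,
* $a_+$ and $a_-$ = per-sign acceleration ECDF values at 90% accumulation
  (the positive threshold from the positive accelerations, the negative
  one as minus the quantile of the negated negative ones).

Two conventions deserve a word:

* **Type-1 quantiles.** The quantile is the smallest *observed* value
  whose cumulative fraction reaches the level — the inverse ECDF with no
  interpolation. Interpolating definitions differ by less than one sample
  spacing, but fixing the convention makes the suggestion exactly
  reproducible and testable.
* **Per-sign acceleration quantiles.** Acceleration distributions from
  real recordings are visibly asymmetric, and the candidate rule uses two
  separate bounds; computing one quantile of $|a_i|$ would force symmetric
  thresholds. Accordingly the two signs are treated separately.

The 85%/90% levels are defaults for visual inspection, not constants of
nature: `histogram_summary()` exposes the distributions with the
thresholds marked, and both levels (or fully manual thresholds) are
configurable. On quiet traces where fixation occupies more than the
default accumulation level, the suggested threshold lands near the top of
the noise bulk — which is the intended behaviour, as the short-saccade
filter below absorbs the resulting one- or two-sample noise crossings.

## Blink handling

Blinks cross any velocity threshold and must be separated from saccades
before fixations are defined.

* **Video.** The pupil disappears during lid closure, but the recorded
  pupil size already ramps down before the gap and ramps back up after
  it. Each maximal missing-pupil gap is extended backward and forward
  along the smoothed pupil derivative until the derivative re-enters a
  noise band (default 2.5 standard deviations of the smoothed derivative,
  estimated at least 200 ms away from any gap; smoothing window 11
  samples). Candidate saccades overlapping a blink are deleted outright —
  gaze coordinates during lid closure are artifact, not movement.
* **EOG.** A blink appears as a large, slow vertical deflection that is
  itself picked up as a candidate saccade. On the amplitude–duration main
  sequence, blinks sit far off the saccade cluster, so a candidate is
  relabeled as a blink when its duration is at least 100 ms **and** its
  main-sequence amplitude is at least twice the median over all
  candidates. Because EOG units are uncalibrated, the amplitude bound
  must be relative; both constants are configurable.
* **Coil.** No blink detection; the trace never shows them.

One measurement subtlety: the *amplitude* of an event is defined as the
Euclidean distance between its endpoint gaze positions, which is the
natural size of a saccade — but a blink deflection returns toward
baseline, so a candidate run spanning a whole blink pulse can have
endpoint amplitude near zero. The main-sequence classifier therefore uses
the candidate's maximum *excursion* from its onset position, which equals
the amplitude for saccades but preserves the blink's true deflection
size. Blink intervals separated by less than 50 ms (the shortest
fixations reported in the literature) are merged: the two supra-threshold
phases of one pulse, split at its velocity zero, are one lid closure.

## Short-saccade filter and overshoot merging

Candidates smaller than 0.1° or briefer than 4 ms are discarded
(inclusive at the boundary: a candidate at exactly 0.1° and 4 ms is
kept). On uncalibrated traces the amplitude bound has no absolute
meaning, so it is either supplied in native units or skipped, leaving the
duration condition.

Overshoots — small corrective movements at the very end of a saccade —
would otherwise be counted as separate saccades and would postpone the
following fixation onset. Two consecutive saccades are merged into one,
flagged `overshoot`, when the gap between them is *strictly* below 16 ms
(well under the ~50 ms shortest fixations, so nothing fixational fits in
between) and the second movement's amplitude is at most 1.5° (inclusive).
Scanning is left-to-right and a merged saccade may merge again with its
successor; the merged amplitude is recomputed from the merged endpoints
and the peak velocity is the pair's maximum. On uncalibrated traces the
amplitude cap is likewise either a configured native-unit value or
dropped (gap-only merging) — a loud caveat, since gap-only merging is
more permissive.

Whether overshoot merging runs before or after the short-saccade filter
is not a settled question; the default applies the filter first (the
order in which the steps are naturally narrated) and
`overshoot.before_filter = TRUE` exposes the other order. The two differ
only when a sub-threshold-size overshoot fragment would itself be
filtered away before it can be merged; both orders produce valid
partitions.

Fixations are then *defined*, not detected: every maximal gap between
consecutive saccades/blinks becomes a fixation, with no minimum-duration
filter, and residual periods at the trace edges are fixations flagged
`truncated`. The resulting event list exactly tiles the trace extent —
an invariant asserted in the test suite for every detection.

## The synthetic free-viewing generator

`simulate_trace()` exists so the whole pipeline can be validated without
recorded data. It emulates the statistics the detector relies on, not
ocular physiology in full:

* **Fixations**: gamma-distributed durations (mean 0.30 s, shape 4 — the
  right-skewed spread typical of free viewing), with 2-D random-walk
  drift of 0.002°/sample at 500 Hz (≈1°/s instantaneous drift speed).
* **Saccades**: amplitudes uniform on 1–15°, displacement following a
  raised-cosine sigmoid (sine-shaped velocity). The profile was chosen
  over a minimum-jerk sigmoid deliberately: minimum-jerk velocity rises
  quadratically from zero, giving an unphysical several-millisecond dead
  zone after movement onset, whereas real saccades launch with abrupt
  acceleration; the sine profile has linear velocity onset and is a
  standard simple saccade model. Peak velocity follows the configured
  main sequence $v_\mathrm{peak} = \max(200, 30A)$ °/s and duration
  follows from the profile, $D = \pi A / (2 v_\mathrm{peak})$, so
  amplitude, duration and peak velocity are mutually consistent
  (durations ≈8–52 ms over the default amplitude range).
* **Overshoots**: a configurable fraction of saccades (default 0.15) is
  followed, within 6–12 ms, by a reverse movement of 0.3–1.0°; ground
  truth records the whole thing as one saccade flagged `overshoot`.
* **Blinks** (default 10/min): on video, the pupil ramps down over 20 ms,
  is missing for the core, and ramps back, with gaze samples missing
  during occlusion; on EOG, a raised-cosine vertical deflection of 45
  degree-equivalents. Full-blink durations are 0.25–0.40 s — besides
  being the physiological range, durations must exceed ≈0.22 s for the
  pulse's two supra-threshold phases (each about half the pulse) to clear
  the 100 ms main-sequence duration boundary.
* **Noise**: additive Gaussian noise of 0.01° per axis (typical video
  eye-tracker noise), doubled for EOG, which also receives a slow
  random-walk baseline drift standing in for electrode drift.

Ground truth stores every event's exact continuous-time onset and offset
and partitions the trace. All randomness flows from one seed (per-trial
seeds in `simulate_session()` are drawn deterministically from the
session seed); detection itself uses none.

One configured tension is worth stating plainly: a *nominal* rate of 3.5
fixations/s and a *mean* fixation duration of 300 ms cannot both hold
once saccades (~43 ms average here) and blinks take their share of the
timeline. The generator honours the duration — the better-defined
physiological quantity — so the realized rate is ≈2.8 saccades/s; the
nominal rate parameter governs only the blink-insertion bookkeeping, and
the count test checks the renewal-process expectation computed from the
configured means.

What passing tests on this generator do **not** show: robustness to
smooth pursuit, head-free recording, vergence, tracker dropout unrelated
to blinks, asymmetric or multi-peaked saccade profiles, or pink-noise
EOG floors — none of which the generator produces. They do show that the
thresholding, grouping, blink separation, filtering, merging and fixation
logic implement their definitions exactly, and that on signals with the
assumed structure the detector's onset timing is accurate to about a
millisecond at 500 Hz.

## Numerical choices and degenerate inputs

* Timestamps are normalized to seconds at load time and actual timestamps
  (not the nominal rate) enter every difference quotient, so dropped
  frames cannot corrupt velocities; a non-positive time step is an error
  naming the index.
* Missing samples propagate: any kinematic entry touching a missing gaze
  sample is missing, is never a candidate, and is excluded before
  quantile computation — missingness never silently becomes spurious
  velocity.
* Interval alignment is half-open forward: $d_i, v_i$ describe the
  interval starting at sample $i$, so a detected onset is the left sample
  of the first supra-threshold interval. The last interval has no
  acceleration and is judged on velocity alone.
* Equality at a threshold counts as crossing, on both acceleration signs.
* Candidate runs separated by a single sub-threshold sample are *not*
  bridged at the grouping stage (gap tolerance zero); the overshoot rule
  is the one place where near-adjacent movements are united.
* Fixation gaps shorter than $10^{-9}$ s are not materialized, so a
  saccade abutting a blink produces no zero-length fixation.
* Event tables are written with full double precision (`%.17g`), making
  the write/read round trip exact.

## Validation problem sizes

The shipped checks use: 20 simulated trials of 3 s at 500 Hz for the
onset-error and recall surface (mean |onset error| ≈ 1.1 ms, well inside
the ±3 ms the detector is designed for; recall of ≥1° saccades = 1.0);
100 random 1.5 s traces across all three modalities for the partition
invariant; 1000 random masks against a brute-force run-length oracle;
1000-sample traces against a per-sample loop oracle for the kinematics;
and 120 s traces for the generator's own duration and main-sequence
statistics. These sizes make the full suite run in well under a minute
while keeping every count large enough to be meaningful.

## Limitations

The detector is a global-threshold method by design: it trades adaptivity
(per-trial λ·SD microsaccade thresholds, HMM or Bayesian event models)
for exact reproducibility. Very small saccades near the noise floor are
deliberately sacrificed by the 0.1°/4 ms filter; smooth pursuit is not
modelled and will be segmented arbitrarily; and on uncalibrated traces
every amplitude-based rule weakens to its native-unit or gap-only form.
A final visual inspection of detections over the raw trace remains good
practice before any downstream analysis.
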
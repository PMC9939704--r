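# safide

Deterministic detection of **saccades, fixations and blinks** from one
eye's sampled trace — video eye tracking (pixels), EOG (uncalibrated
volts/arbitrary units) or scleral search coil recordings — plus a
synthetic free-viewing simulator with ground truth and an event-matching
evaluator.

The package is for eye-movement and cognitive-neuroscience researchers
who need event detection that is *exactly reproducible*: the detector
contains no randomness, no iterative fitting and no hidden smoothing, so
the same trace and parameters always produce byte-identical events —
which matters whenever brain activity is time-locked to saccade or
fixation onset, or event rates are compared across subjects and setups.

## The method

From gaze positions $(x_i, y_i)$ at times $t_i$:

$$d_i = \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}, \quad
  v_i = \frac{d_i}{t_{i+1}-t_i}, \quad
  a_i = \frac{v_{i+1}-v_i}{t_{i+1}-t_i}$$

with optional pixel→degree conversion. A sample is a **candidate
saccade** when $v_i \ge v_\mathrm{thr}$ or $a_i \ge a_+$ or
$a_i \le a_-$; thresholds are suggested from the trace's own empirical
distribution functions (type-1 quantiles at 85% accumulation for
velocity, 90% per sign for acceleration), reflecting that the eye
fixates 80–90% of the time during free viewing. Consecutive candidates
form candidate saccades; blinks are removed (pupillometry-noise gaps for
video, amplitude–duration main-sequence separation for EOG); candidates
below 0.1° or 4 ms are discarded; post-saccadic **overshoots** (gap
< 16 ms, second amplitude ≤ 1.5°) are merged back into their parent
saccade; and **fixations** are the residual periods, so the labeled
events exactly tile the recording.

## Worked example

```r
library(safide)

# simulate 3 s of free viewing at 500 Hz, then detect
st <- simulate_trace(sim_config(duration = 3, seed = 5))
ev <- detect(st$trace)
attr(ev, "thresholds")
#> <threshold_set> (suggested)
#>   velocity     >= 19.6535 units/s   [ECDF level 0.85]
#>   acceleration >= 8130.74 or <= -8624.9 units/s^2   [ECDF level 0.90]
ev
#> <safide_events> 21 events on [0.000, 3.000] s: saccade=10, fixation=11, blink=0
#>    onset offset    label amplitude duration peak_velocity overshoot truncated
#> 1  0.000  0.252 fixation        NA    0.252            NA     FALSE      TRUE
#> ...

match_events(ev, st$truth, label = "saccade")
#> <match_report> label: saccade
#>   truth 10 | detected 10 | hits 10 | misses 0 | false alarms 0
#>   recall 1.000 | precision 1.000 | mean |onset error| 1.21 ms
```

The suggested velocity threshold (~19.7 deg/s here) sits just above the
fixational drift-plus-noise bulk of this trace's velocity distribution;
all ten injected saccades are recovered, with onsets about one sample
off on average. For real data, read a delimited export with
`read_gaze_samples()` and a `gaze_format()` column map, and inspect
`histogram_summary()` before trusting suggested thresholds.

A thin command-line wrapper is installed at `exec/safide`:

```sh
safide simulate --seed 1 --out sim --trials 3
safide detect sim/trial01_samples.csv --fs 500 --ppd 39.38 \
       --pupil pupil --out events.tsv
safide thresholds sim/trial01_samples.csv --fs 500 --ppd 39.38
safide evaluate events.tsv sim/trial01_truth.tsv --label saccade
```

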
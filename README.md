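# nfeemd

Heart-rate estimation from a single wrist photoplethysmography (PPG)
channel during intense physical activity, using simultaneous tri-axis
acceleration to detect and remove motion artifacts.

Wearable PPG encodes heart rate as the dominant spectral peak of the
pulsatile signal in 0.5–3 Hz (30–180 BPM). Motion corrupts that spectrum
with artifact tones that can mask or exactly overlap the cardiac peak —
but the same tones appear in the accelerometer spectra, which is the
lever this package pulls. Intended users are researchers working with
wrist-worn PPG + accelerometer recordings (e.g. the IEEE Signal
Processing Cup wrist datasets, whose MAT layout is read natively) and
anyone needing a transparent, scriptable reference implementation of
notch/EEMD-based artifact removal.

## Method

Each 8-s window (2-s stride) is routed by a decision tree:

- **No motion** (some acceleration axis quiet): highest peak of the
  band-passed PPG, gated to within `th_pass = 8` BPM of the previous
  estimate `bpm_prev`.
- **Motion, unusable acceleration** (> 5 peaks on an axis): hold
  `bpm_prev`.
- **Motion, usable acceleration**: PPG peaks within 8 BPM of any
  acceleration peak are deleted. One survivor → gate it; several → take
  the one closest to `bpm_prev`; none (cardiac peak masked) → recover
  with
  1. a cascade of ≤ 3 second-order IIR single-notch filters
     `H(z) = (1 − 2cos w₀ z⁻¹ + z⁻²)/(1 − 2r cos w₀ z⁻¹ + r² z⁻²)`,
     `r = 0.96`, one per artifact frequency, then
  2. if the notch estimate is implausible, ensemble empirical mode
     decomposition (Ne = 5, noise ratio 0.05) with rank-1 singular
     spectrum analysis (L = 150) per IMF, selecting the IMF whose cycle
     is closest to `bpm_prev`.
- **Calibrations**: after repeated fallbacks without motion, re-estimate
  from the raw periodogram; during motion, a GM(1,1) grey-model forecast
  of recent estimates (or three consecutive fallbacks) triggers a notch
  re-estimate accepted within 40 BPM — this is what re-locks the tracker
  when heart rate keeps rising under sustained corruption.
- The reported series is a 5-window moving average of the raw estimates.

Accuracy is summarized by AAE `mean|est − truth|`, AEP
`mean(|est − truth|/truth)·100`, Bland–Altman limits of agreement
`μ ± 1.96σ` of the differences, and Pearson correlation.

## Worked example

```r
library(nfeemd)

# 5-minute synthetic treadmill session: rest -> moderate -> fast -> ... ,
# cadence-locked artifact tones during the motion segments
g <- gen_record(gen_activity_profile("t0_type01", seed = 1))
res <- run_pipeline(g$record, tracker_config(), seed = 1)
head(res[res$route != "INIT", c("window_index", "time_s", "bpm_est",
                                "bpm_true", "route")])
evaluate_result(res)[c("aae", "mean_diff", "loa", "pearson_r")]
```

```
  window_index time_s  bpm_est bpm_true       route
1            0      0 75.07324       75 INIT_ACCEPT
2            1      2 75.07324       75       CASE1
3            2      4 75.07324       75       CASE1
4            3      6 75.07324       75       CASE1
5            4      8 75.07324       75       CASE1
6            5     10 75.07324       75       CASE1

$aae
[1] 2.279799
$mean_diff
[1] -0.9177209
$loa
[1] -6.718954  4.883512
$pearson_r
[1] 0.9933226
```

The tracker follows the 75→150 BPM profile with an average absolute
error of 2.3 BPM; the residual error is mostly the smoothing lag on the
ramps (the raw, pre-smoothing AAE is 0.6 BPM). On real recordings, load
data with `load_spcup_record("DATA_01_TYPE01.mat", truth_path = ...)` or
`load_csv_record()` and call `run_pipeline()` the same way.

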
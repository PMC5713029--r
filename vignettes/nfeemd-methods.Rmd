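---
title: "Heart-rate tracking from motion-corrupted wrist PPG: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate tracking from motion-corrupted wrist PPG: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfeemd)
```

## The problem

A wrist photoplethysmogram (PPG) encodes heart rate as the dominant
spectral peak of its pulsatile component, normally inside 0.5–3 Hz
(30–180 BPM). During running, boxing or arm exercise, sensor–skin motion
injects artifact tones that can dwarf — or exactly overlap — the cardiac
peak, so naive peak picking derails. The saving grace is that the same
motion is visible in a simultaneously recorded tri-axis accelerometer:
artifact frequencies appear in the acceleration periodograms, cardiac
frequencies do not.

`nfeemd` estimates one heart-rate value per 8-s analysis window (2-s
stride, 6-s overlap) from one PPG channel plus three acceleration
channels, all sampled at a common rate (125 Hz by convention). Rather than
pushing every window through the same heavy machinery, a decision tree
routes each window to the cheapest treatment its corruption level permits.

## The per-window decision tree

All spectra are 4096-point rectangular-window periodograms normalized as
one-sided PSD (`|X|^2 / (N fs)`, interior bins doubled, so power
integrates to the mean square). "Peaks" are strict local maxima in
0.5–3 Hz whose amplitude exceeds 30% of the in-band maximum.

1. **Initialization.** Windows are scanned until the *raw* PPG
   periodogram has exactly one in-band peak; that BPM seeds `bpm_prev`.
   Earlier windows are discarded (reported `NA`): a multi-peak start
   would seed a wrong prior, and heart rate cannot change fast enough for
   a short discard to matter.
2. **Motion detection.** Artifacts are present when *every* axis has
   in-band PSD amplitude above `acc_amp_thresh` (default 0.1). The
   conjunction matters: genuine arm motion shakes all axes, while sensor
   noise on one axis does not. The threshold's scale is tied to this
   package's PSD normalization of mean-removed acceleration; rest
   segments with acceleration noise SD of a few hundredths sit orders of
   magnitude below it, sustained tones of near-unit amplitude sit well
   above.
3. **No artifacts (Case 1).** The highest peak of the band-passed PPG is
   accepted if within `th_pass = 8` BPM of `bpm_prev`, else the past
   value is held. After two consecutive holds, **Calibration 1**
   re-estimates from the raw periodogram and *adopts* the new peak
   precisely when it is far from the held value — the escape hatch from a
   stuck estimate.
4. **Artifacts present.** If any acceleration axis shows more than
   `th_acc_peaks = 5` peaks its spectrum is too messy to name the
   artifact frequencies: the window is unreliable (Case 2) and holds the
   past value. Otherwise every PPG peak within 8 BPM (inclusive) of any
   acceleration peak is deleted, and the count of survivors routes the
   window: one survivor is gated like Case 1 (Case 4); several survivors
   are first reduced to those within `th_pass` of `bpm_prev` (zero, one,
   many → Cases 3/4/5, the "ternary decisions"); Case 5 takes the peak
   closest to `bpm_prev` (ties toward the lower BPM). Zero survivors is
   the hard case.
5. **Masked cardiac peak (Case 3).** Two recovery paths, tried in order:
   - *Repeated single notch.* One second-order IIR notch
     (`H(z) = (1 - 2cos(w0) z^-1 + z^-2) / (1 - 2 r cos(w0) z^-1 + r^2 z^-2)`,
     `r = 0.96`) per distinct artifact frequency, at most three; beyond
     three, one notch per axis at its largest peak. The zero sits *on*
     the unit circle, so the artifact tone is annihilated while a cardiac
     tone ≥ 0.2 Hz away survives. The estimate is the dominant in-band
     peak of the filtered window, accepted within `th_NF` of `bpm_prev`
     (15 BPM after the first ternary decision, 10 after the second) and
     within the absolute 30-BPM off-track guard.
   - *EEMD + SSA.* If notching fails (typically because the artifact
     overlaps the cardiac frequency and the notch removed both), the
     *raw* window is decomposed by ensemble empirical mode decomposition
     (ensemble 5, noise SD 5% of signal SD), each IMF is denoised by
     rank-1 singular spectrum analysis (embedding 150 samples), and the
     IMF whose dominant cycle is closest to `bpm_prev` provides the
     estimate, gated by `th_EEMD` (15/10 BPM) and the same guard.
   - Otherwise the past value is held.
6. **Calibration 2.** Sustained artifact corruption plus a drifting heart
   rate is the classic derailment: every window holds `bpm_prev` while
   truth walks away. When a window falls back during motion and either
   (a) a GM(1,1) grey-model forecast of the last ≤ 30 raw estimates
   disagrees with the held value by more than 12 BPM, or (b) three
   consecutive artifact-time holds have accumulated, the rate is
   re-estimated through the notch cascade and accepted within a wide
   40-BPM gate. The two triggers are OR-ed; the prose describing them is
   ambiguous, and OR is the reading under which the mechanism can fire at
   all when the stalled history is flat (a flat history makes the grey
   forecast equal the held value, so only the counter trigger works).
7. **Smoothing.** The reported series is the mean of the last 5 raw
   estimates (length configurable; the method prescribes a cyclic moving
   average without a length).

Acceptance direction: the published gate inequalities are phrased as
"difference greater than threshold"; they are implemented as *rejection*
conditions (an estimate farther than the gate from `bpm_prev` is
rejected), which is the only direction under which the cases cohere.
Ternary decision 2 refines the "more than one survivor" branch; attaching
it to the single-survivor branch (as one prose passage suggests) would
leave Cases 4/5 unreachable.

## Numerical choices

- **Band-pass pre-processing** is a cascade of centered moving averages
  with reflection padding, two passes per stage: a short stage
  (`round(fs/(2*high))` samples) low-passes, a long stage
  (`round(fs/low)` samples) estimates the baseline that is subtracted.
  The long stage's first null sits on the lower band edge. The short
  stage's null is placed at *twice* the upper edge: placing it on the
  edge itself would drag mid-band gain to ~0.4, defeating the passband.
  Measured gains: ~0.8 at 1.5 Hz, < 0.15 above 5 Hz, DC removed exactly.
  The filter is linear and zero-phase by construction.
- **Sifting** stops when the normalized squared difference between
  successive sifts falls below 0.2 *and* the candidate satisfies the IMF
  condition (|extrema − zero crossings| ≤ 1); envelopes are cubic splines
  through the extrema with two extrema mirrored at each end. The
  iteration cap is 200: typical IMFs converge in under 20 sifts, but the
  mode condition occasionally needs ~100, and a cap of 50 would return
  invalid modes. Extraction stops when the residual has fewer than two
  maxima or minima, so a monotone input yields zero IMFs and an exact
  residue.
- **EEMD averaging** aligns IMFs by index and zero-pads members with
  fewer modes; the residues are averaged likewise. All ensemble noise is
  drawn under a caller-supplied seed (the pipeline derives one seed per
  window from its master seed), and the caller's RNG state is restored —
  a fixed seed gives bit-identical output.
- **SSA rank-1 reconstruction** uses the exact SVD of the L×(N−L+1)
  trajectory matrix and anti-diagonal averaging computed by open
  convolution of the leading singular vectors (O(N log N), no dense
  rank-1 matrix).
- **Notch filtering** is a single causal pass with zero initial state; at
  `r = 0.96` and 125 Hz the startup transient decays in well under 2 s of
  the 8-s window. Notch cascades commute (LTI), duplicated frequencies
  are collapsed first.
- **GM(1,1)** fits the whitening equation by least squares on the
  cumulated series; `|a| < 1e-10` degenerates to the constant forecast.
  The model is exact on geometric series; on a linear ramp the fitted
  exponential slightly overshoots the linear continuation (162.3 for
  100, 102, …, 158), which is inherent to the model, not an
  implementation artifact.
- **Degenerate inputs**: all-zero spectra yield empty peak sets; a flat
  spectrum degenerates to its band maximum; a silent IMF has no defined
  cycle and is excluded from selection; if no IMF has a cycle the tracker
  falls back to `bpm_prev`.

## What the synthetic generator emulates — and what it does not

`gen_record()` builds PPG as a harmonic series (default amplitudes 1 and
0.5) of a chirp whose instantaneous frequency integrates the prescribed
BPM trajectory, plus artifact tones, plus white noise; each acceleration
axis receives the same artifact tones with independent random amplitudes
and phases plus low noise. Rest segments carry no tones, so acceleration
power stays below the motion threshold. Per-window truth is the mean
instantaneous BPM over exactly the tracker's windows.

The canned treadmill profiles map the benchmark protocol's speeds to
plateau heart rates (rest 75; moderate 120/110; fast 150/140 BPM) with
30–40 s transitions after each speed change — sustained slopes near
1 BPM/s, consistent with heart-rate on/off kinetics; the closing 30-s
rest segment therefore ends mid-recovery rather than back at baseline.
Cadence-locked artifact tones (e.g. 1.4/2.8 Hz) run through the motion
segments. The stress scenarios reproduce three published failure regimes:
artifact tones masking a 163-BPM heart rate (notch recovery), an
artifact sitting exactly on the cardiac frequency with a stronger
low-frequency partner (decomposition recovery), and a heart-rate ramp
under broadband, peakless acceleration (calibration recovery).

What the generator does *not* model: pulse-waveform morphology (dicrotic
notch, amplitude modulation), baseline wander from venous motion,
non-stationary artifact chirps within a window, sensor saturation, and
arrhythmia. Passing tests therefore demonstrate that the machinery
implements the method correctly and recovers the engineered regimes —
not that field accuracy on real wrist recordings equals the synthetic
numbers. Readers with the competition recordings can run them through
`load_spcup_record()` and `run_pipeline()` unchanged.

## Problem sizes used by the tests

The validation suite runs records of 170–300 s at 125 Hz (about 80–150
windows each), 50 random smooth 1000-sample signals for the
decomposition oracle, and 20 random designs for the notch oracle. These
sizes keep the full suite under a minute while leaving every code path
exercised on realistic window counts.

## Known limitations

- Initialization requires some artifact-free (or single-peaked) window;
  a record that starts mid-boxing may discard many windows.
- The motion-detection threshold is in PSD units of this package's
  normalization; recordings with very different gain conventions may
  need `acc_amp_thresh` rescaled.
- The single-pass causal notch leaves a small transient resonance at the
  notched frequency; with the default window length this is dominated by
  any surviving cardiac tone, but for very short windows a
  forward–backward (zero-phase) variant would be preferable.
- EMD separates tones reliably when their frequency ratio is below
  ~0.6; artifact tones within ~20% of the cardiac frequency (but not
  overlapping) are the hardest regime for the decomposition path — the
  notch path usually handles them instead.
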
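# --- Synthetic record generator -------------------------------------------
#
# Emulates the structure of wrist PPG recordings during exercise: a
# quasi-periodic pulse wave (fundamental plus harmonics) following a
# prescribed BPM trajectory, additive sinusoidal motion-artifact tones whose
# frequencies also appear (with independent amplitudes/phases) in all three
# acceleration channels, broadband noise, and rest segments with negligible
# acceleration power.

#' Build a synthetic-record configuration
#'
#' @param duration record length in seconds (>= 16).
#' @param fs sampling rate in Hz (default 125).
#' @param bpm_trajectory data frame with columns `time` (s) and `bpm`;
#'   piecewise-linear control points of the heart-rate trajectory, which
#'   must stay inside (30, 240) BPM.
#' @param ppg_harmonics amplitudes of the pulse fundamental and harmonics
#'   (default `c(1, 0.5)`).
#' @param ma_tones list of motion-artifact tones; each a list with `freq`
#'   (Hz, or the string `"hr"` to track the instantaneous heart-rate
#'   frequency — the fully-overlapped regime), `amp_ppg`, `amp_acc`,
#'   `start`, `end` (seconds). Tones switch on/off with a 1-s linear taper.
#' @param acc_noise_sd broadband noise SD on each acceleration axis
#'   (default 0.02, low enough that rest windows stay below the motion
#'   detector's threshold).
#' @param ppg_noise_sd broadband noise SD on the PPG (default 0.05).
#' @param acc_chaos optional list of segments `list(start, end, sd)` during
#'   which strong broadband noise is injected into all acceleration axes
#'   (emulates erratic arm movement whose spectrum has no clean peaks).
#' @param seed RNG seed; the generated record is a deterministic function
#'   of the configuration.
#' @param id record label.
#' @return a `synth_config` list.
#' @export
synth_config <- function(duration, fs = 125,
                         bpm_trajectory = data.frame(time = c(0, duration),
                                                     bpm = c(72, 72)),
                         ppg_harmonics = c(1, 0.5),
                         ma_tones = list(),
                         acc_noise_sd = 0.02,
                         ppg_noise_sd = 0.05,
                         acc_chaos = list(),
                         seed = 1L,
                         id = "synthetic") {
  if (duration < 16) stop("duration must be at least 16 s")
  stopifnot(all(c("time", "bpm") %in% names(bpm_trajectory)))
  if (any(bpm_trajectory$bpm <= 30) || any(bpm_trajectory$bpm >= 240)) {
    stop("bpm trajectory must stay inside (30, 240) BPM")
  }
  structure(list(duration = duration, fs = fs,
                 bpm_trajectory = bpm_trajectory,
                 ppg_harmonics = ppg_harmonics, ma_tones = ma_tones,
                 acc_noise_sd = acc_noise_sd, ppg_noise_sd = ppg_noise_sd,
                 acc_chaos = acc_chaos, seed = seed, id = id),
            class = "synth_config")
}

# 1-s linear on/off taper for a tone active on [start, end].
tone_gate <- function(t, start, end, taper = 1) {
  g <- pmin(pmax((t - start) / taper, 0), 1) *
    pmin(pmax((end - t) / taper, 0), 1)
  pmin(g, 1)
}

#' Generate a synthetic record with known ground truth
#'
#' The PPG instantaneous phase integrates the BPM trajectory (a chirp), so
#' heart-rate ramps are physiologic rather than stepwise. Per-window ground
#' truth is the mean instantaneous BPM over each analysis window, windowed
#' exactly as [slide_windows()] does.
#'
#' @param cfg a [synth_config()].
#' @param win_seconds,step_seconds windowing used for the truth trace
#'   (defaults 8 and 2, matching the tracker).
#' @return list with `record` (an `nfeemd_record`, `truth_bpm` attached)
#'   and `truth` (data frame `window_index`, `time_s`, `bpm`).
#' @export
gen_record <- function(cfg, win_seconds = 8, step_seconds = 2) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  t <- (0:(n - 1L)) / fs
  bpm_t <- stats::approx(cfg$bpm_trajectory$time, cfg$bpm_trajectory$bpm,
                         xout = t, rule = 2)$y
  f_hr <- bpm_t / 60
  phase_hr <- 2 * pi * cumsum(f_hr) / fs
  with_local_seed(cfg$seed, {
    ppg <- rep(0, n)
    for (h in seq_along(cfg$ppg_harmonics)) {
      ppg <- ppg + cfg$ppg_harmonics[h] * sin(h * phase_hr + stats::runif(1, 0, 2 * pi))
    }
    acc <- list(x = rep(0, n), y = rep(0, n), z = rep(0, n))
    for (tone in cfg$ma_tones) {
      gate <- tone_gate(t, tone$start, tone$end)
      ph <- if (identical(tone$freq, "hr")) phase_hr
            else 2 * pi * tone$freq * t
      ppg <- ppg + tone$amp_ppg * gate * sin(ph + stats::runif(1, 0, 2 * pi))
      for (ax in names(acc)) {
        amp <- tone$amp_acc * stats::runif(1, 0.7, 1.3)
        acc[[ax]] <- acc[[ax]] + amp * gate * sin(ph + stats::runif(1, 0, 2 * pi))
      }
    }
    for (seg in cfg$acc_chaos) {
      gate <- tone_gate(t, seg$start, seg$end)
      for (ax in names(acc)) {
        acc[[ax]] <- acc[[ax]] + gate * stats::rnorm(n, 0, seg$sd)
      }
    }
    ppg <- ppg + stats::rnorm(n, 0, cfg$ppg_noise_sd)
    for (ax in names(acc)) {
      acc[[ax]] <- acc[[ax]] + stats::rnorm(n, 0, cfg$acc_noise_sd)
    }
    W <- round(win_seconds * fs)
    S <- round(step_seconds * fs)
    n_win <- (n - W) %/% S + 1L
    truth <- vapply(seq_len(n_win) - 1L, function(i) {
      mean(bpm_t[(i * S + 1L):(i * S + W)])
    }, numeric(1))
    record <- new_record(ppg, acc$x, acc$y, acc$z, fs = fs,
                         truth_bpm = truth, id = cfg$id)
    list(record = record,
         truth = data.frame(window_index = seq_len(n_win) - 1L,
                            time_s = (seq_len(n_win) - 1L) * step_seconds,
                            bpm = truth))
  })
}

#' Canned activity-profile configurations
#'
#' Emulates the treadmill protocols of wrist-PPG benchmark recordings as
#' BPM trajectories (speeds mapped to plateau heart rates, 30-s
#' physiological ramps between them) with cadence-locked artifact tones in
#' the PPG and acceleration during the motion segments:
#' * `"t0_type01"` — rest (30 s) / moderate run / fast run / moderate /
#'   fast / rest; plateaus 75, 120, 150, 123, 150, decaying to 95 BPM over
#'   a 5-min record; cadence tones at 1.4 and 2.8 Hz.
#' * `"t0_type02"` — slower variant: plateaus 75, 110, 140, 112, 140 BPM;
#'   cadence tones at 1.3 and 2.6 Hz.
#' * `"t1_random"` — randomized plateau jumps with a chirp-like artifact
#'   (surrogate of erratic arm exercise), reproducible from the seed.
#'
#' @param kind one of `"t0_type01"`, `"t0_type02"`, `"t1_random"`.
#' @param seed RNG seed stored in the configuration.
#' @return a `synth_config`.
#' @export
gen_activity_profile <- function(kind = c("t0_type01", "t0_type02",
                                          "t1_random"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "t0_type01" || kind == "t0_type02") {
    hi <- if (kind == "t0_type01") c(120, 150, 123, 150) else c(110, 140, 112, 140)
    cad <- if (kind == "t0_type01") c(1.4, 2.8) else c(1.3, 2.6)
    # speed changes at t = 30/90/150/210/270 s; the heart rate follows with
    # on/off kinetics of roughly 30-40 s (sustained slopes near 1 BPM/s)
    traj <- data.frame(
      time = c(0, 30, 70, 90, 118, 150, 178, 210, 238, 270, 300),
      bpm = c(75, 75, hi[1], hi[1], hi[2], hi[2], hi[3], hi[3],
               hi[4], hi[4], hi[4] - 30))
    tones <- list(
      list(freq = cad[1], amp_ppg = 0.8, amp_acc = 1.0, start = 30, end = 270),
      list(freq = cad[2], amp_ppg = 0.6, amp_acc = 0.8, start = 30, end = 270))
    return(synth_config(duration = 300, bpm_trajectory = traj,
                        ma_tones = tones, seed = seed, id = kind))
  }
  # t1_random: jumpy trajectory + slowly sweeping artifact tone
  with_local_seed(seed, {
    times <- seq(0, 300, by = 30)
    bpm <- pmin(pmax(cumsum(c(90, stats::runif(length(times) - 1, -20, 25))),
                     60), 185)
    traj <- data.frame(time = times, bpm = bpm)
    tones <- list(
      list(freq = stats::runif(1, 1.0, 1.6), amp_ppg = 1.2, amp_acc = 1.0,
           start = 20, end = 290),
      list(freq = stats::runif(1, 2.0, 2.9), amp_ppg = 0.9, amp_acc = 0.9,
           start = 20, end = 290))
    synth_config(duration = 300, bpm_trajectory = traj, ma_tones = tones,
                 seed = seed, id = kind)
  })
}

#' Named stress-test scenarios for the artifact-removal machinery
#'
#' Each scenario reproduces, on synthetic data, one qualitative regime of
#' motion-corrupted PPG:
#' * `"notch_regime"` — constant 163-BPM heart rate masked by two strong
#'   artifact tones at 1.43 and 2.87 Hz (86.06 / 172.1 BPM) that dwarf the
#'   cardiac peak; the notch cascade must excise them. 3-min record with a
#'   16-s artifact-free lead-in for tracker initialization.
#' @param kind scenario name.
#' @param seed RNG seed.
#' @details
#' * `"overlap_regime"` — the dominant artifact tone sits exactly on the
#'   heart-rate frequency (near 154 BPM) with a second, stronger tone at
#'   1.28 Hz; notching removes the cardiac component together with the
#'   artifact, so recovery must come from the decomposition path.
#' * `"tracker_stall"` — heart rate ramps 80 to 140 BPM while the
#'   acceleration spectra are saturated with broadband motion (no usable
#'   artifact peaks); every window falls back to the past estimate and only
#'   the calibration stage can re-lock the tracker.
#' @return a `synth_config`.
#' @export
gen_scenario <- function(kind = c("notch_regime", "overlap_regime",
                                  "tracker_stall"), seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    notch_regime = synth_config(
      duration = 180,
      bpm_trajectory = data.frame(time = c(0, 180), bpm = c(163, 163)),
      ppg_harmonics = c(1, 0.3),
      ma_tones = list(
        list(freq = 1.43, amp_ppg = 4, amp_acc = 1, start = 16, end = 180),
        list(freq = 2.87, amp_ppg = 4, amp_acc = 1, start = 16, end = 180)),
      seed = seed, id = kind),
    overlap_regime = synth_config(
      duration = 180,
      bpm_trajectory = data.frame(time = c(0, 20, 60, 180),
                                  bpm = c(150, 150, 154, 154)),
      ppg_harmonics = c(1, 0.3),
      ma_tones = list(
        list(freq = "hr", amp_ppg = 2, amp_acc = 1, start = 16, end = 180),
        list(freq = 1.28, amp_ppg = 6, amp_acc = 1.2, start = 16, end = 180)),
      seed = seed, id = kind),
    tracker_stall = synth_config(
      duration = 170,
      bpm_trajectory = data.frame(time = c(0, 20, 140, 170),
                                  bpm = c(80, 80, 140, 140)),
      ppg_harmonics = c(1, 0.4),
      acc_chaos = list(list(start = 20, end = 170, sd = 3)),
      seed = seed, id = kind))
}
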
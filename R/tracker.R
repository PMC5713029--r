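# --- Heart-rate tracking state machine ------------------------------------

#' Tracker configuration
#'
#' All tunable constants of the pipeline in one validated list. The
#' defaults are the published operating point of the method: 8-s windows
#' with 2-s stride at 125 Hz, 4096-point rectangular-window periodograms,
#' the 30% relative peak threshold, `th_pass = 8` BPM, per-axis peak-count
#' reliability cap of 5, notch/decomposition acceptance gates of 15 BPM
#' (after the first ternary decision) and 10 BPM (after the second), an
#' absolute 30-BPM off-track guard in the artifact-removal case, notch pole
#' radius 0.96, ensemble size 5 with 0.05 noise ratio, SSA window 150, and
#' the calibration constants 12 (grey-prediction gap) and 40 BPM
#' (re-estimate acceptance).
#'
#' @param th_pass peak acceptance gate vs. the previous estimate (BPM).
#' @param th_acc_peaks per-axis acceleration peak-count reliability cap.
#' @param th_nf_1,th_eemd_1 notch / decomposition acceptance gates (BPM)
#'   when the masked-peak case was reached from the first ternary decision.
#' @param th_nf_2,th_eemd_2 same gates for the second ternary decision.
#' @param th_off absolute off-track guard (BPM) on any masked-peak-case
#'   estimate.
#' @param acc_amp_thresh acceleration PSD amplitude threshold for motion
#'   detection.
#' @param peak_match_tol BPM tolerance when matching PPG peaks to
#'   acceleration peaks (inclusive).
#' @param max_notches notch cascade depth cap.
#' @param calib2_pred_gap grey-model prediction gap (BPM) triggering the
#'   second calibration.
#' @param calib2_accept acceptance bound (BPM) of the second calibration's
#'   re-estimate.
#' @param gm_history number of recent raw estimates fed to the grey model.
#' @param smooth_window output moving-average length in windows.
#' @param rel_thresh relative spectral-peak threshold (fraction of the band
#'   maximum).
#' @param band peak-search band in Hz.
#' @param nfft periodogram FFT length.
#' @param notch_r notch pole radius.
#' @param eemd_ne,eemd_noise_ratio ensemble size and noise ratio.
#' @param max_sift,sift_tol sifting controls.
#' @param ssa_L SSA embedding window (samples).
#' @param win_seconds,step_seconds analysis windowing.
#' @param use_calibration2 enable the second calibration stage (default
#'   TRUE; switchable for ablation).
#' @return a validated `tracker_config` list.
#' @export
tracker_config <- function(th_pass = 8, th_acc_peaks = 5L,
                           th_nf_1 = 15, th_eemd_1 = 15,
                           th_nf_2 = 10, th_eemd_2 = 10,
                           th_off = 30, acc_amp_thresh = 0.1,
                           peak_match_tol = 8, max_notches = 3L,
                           calib2_pred_gap = 12, calib2_accept = 40,
                           gm_history = 30L, smooth_window = 5L,
                           rel_thresh = 0.30, band = c(0.5, 3),
                           nfft = 4096L, notch_r = 0.96,
                           eemd_ne = 5L, eemd_noise_ratio = 0.05,
                           max_sift = 200L, sift_tol = 0.2, ssa_L = 150L,
                           win_seconds = 8, step_seconds = 2,
                           use_calibration2 = TRUE) {
  cfg <- list(th_pass = th_pass, th_acc_peaks = th_acc_peaks,
              th_nf_1 = th_nf_1, th_eemd_1 = th_eemd_1,
              th_nf_2 = th_nf_2, th_eemd_2 = th_eemd_2,
              th_off = th_off, acc_amp_thresh = acc_amp_thresh,
              peak_match_tol = peak_match_tol, max_notches = max_notches,
              calib2_pred_gap = calib2_pred_gap,
              calib2_accept = calib2_accept, gm_history = gm_history,
              smooth_window = smooth_window, rel_thresh = rel_thresh,
              band = band, nfft = nfft, notch_r = notch_r,
              eemd_ne = eemd_ne, eemd_noise_ratio = eemd_noise_ratio,
              max_sift = max_sift, sift_tol = sift_tol, ssa_L = ssa_L,
              win_seconds = win_seconds, step_seconds = step_seconds,
              use_calibration2 = isTRUE(use_calibration2))
  positive <- c("th_pass", "th_acc_peaks", "th_nf_1", "th_eemd_1",
                "th_nf_2", "th_eemd_2", "th_off", "acc_amp_thresh",
                "peak_match_tol", "max_notches", "calib2_pred_gap",
                "calib2_accept", "gm_history", "smooth_window",
                "rel_thresh", "nfft", "eemd_ne", "max_sift", "sift_tol",
                "ssa_L", "win_seconds", "step_seconds")
  for (nm in positive) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L ||
        !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("configuration field '", nm, "' must be a positive number")
    }
  }
  if (cfg$notch_r < 0 || cfg$notch_r >= 1) stop("notch_r must be in [0, 1)")
  if (cfg$eemd_noise_ratio < 0) stop("eemd_noise_ratio must be >= 0")
  if (length(cfg$band) != 2L || cfg$band[1] >= cfg$band[2]) {
    stop("band must be an increasing length-2 numeric")
  }
  structure(cfg, class = "tracker_config")
}

#' Initialize the tracker on a window sequence
#'
#' Scans windows until one whose raw-PPG periodogram carries exactly one
#' 30%-peak in band; that peak's BPM seeds `bpm_prev` (stable-tracking
#' entry). Estimates for earlier windows are discarded (reported as NA):
#' a contaminated multi-peak start would seed wrong prior information.
#'
#' @param windows list of `nfeemd_window` (from [slide_windows()]).
#' @param cfg a [tracker_config()].
#' @return list with `index` (0-based window index of the first accepted
#'   window) and `bpm` (its estimate).
#' @export
initialize_tracker <- function(windows, cfg = tracker_config()) {
  if (length(windows) == 0L) stop("no windows to initialize on")
  for (w in windows) {
    spec <- periodogram_spec(w$ppg, w$fs, nfft = cfg$nfft)
    pk <- find_spec_peaks(spec, rel_thresh = cfg$rel_thresh, band = cfg$band)
    if (nrow(pk) == 1L) {
      return(list(index = w$index, bpm = pk$bpm[1L]))
    }
  }
  stop("tracker initialization failed: no window with a single spectral peak")
}

# Single-peak acceptance used by cases 1/4/5: strict gate against the
# previous estimate.
gate_strict <- function(candidate, bpm_prev, th) {
  if (is.finite(candidate) && abs(candidate - bpm_prev) < th) {
    list(bpm = candidate, accepted = TRUE)
  } else {
    list(bpm = bpm_prev, accepted = FALSE)
  }
}

# Case 3 estimator: repeated notch first, decomposition fallback.
# Returns list(bpm, accepted, method).
case3_estimate <- function(window, bpm_prev, level, acc_peaksets, cfg,
                           eemd_seed = NULL) {
  th_nf <- if (level == 1L) cfg$th_nf_1 else cfg$th_nf_2
  th_eemd <- if (level == 1L) cfg$th_eemd_1 else cfg$th_eemd_2
  ma_freqs <- unique(unlist(lapply(acc_peaksets, function(p) p$freq),
                            use.names = FALSE))
  notched <- repeated_notch(window$ppg, ma_freqs, window$fs, r = cfg$notch_r,
                            max_notches = cfg$max_notches,
                            acc_peaksets = acc_peaksets)
  bpm_nf <- top_peak_bpm(notched, window$fs, cfg)
  if (is.finite(bpm_nf) && abs(bpm_nf - bpm_prev) <= th_nf &&
      abs(bpm_nf - bpm_prev) <= cfg$th_off) {
    return(list(bpm = bpm_nf, accepted = TRUE, method = "NF"))
  }
  bpm_eemd <- tryCatch({
    imfset <- eemd(window$ppg, ne = cfg$eemd_ne,
                   noise_sd_ratio = cfg$eemd_noise_ratio, seed = eemd_seed,
                   max_sift = cfg$max_sift, sift_tol = cfg$sift_tol)
    sel <- select_imf(imfset, bpm_prev, window$fs, ssa_L = cfg$ssa_L,
                      nfft = cfg$nfft)
    sel$cycle
  }, error = function(e) NA_real_)
  if (is.finite(bpm_eemd) && abs(bpm_eemd - bpm_prev) <= th_eemd &&
      abs(bpm_eemd - bpm_prev) <= cfg$th_off) {
    return(list(bpm = bpm_eemd, accepted = TRUE, method = "EEMD"))
  }
  list(bpm = bpm_prev, accepted = FALSE, method = "FALLBACK")
}

#' Cyclic moving-average output smoothing
#'
#' The reported heart rate of the current window is the mean of the last
#' `window` raw (pre-smoothing) estimates, or of the full history when it
#' is still shorter.
#'
#' @param raw_history numeric vector of raw per-window estimates.
#' @param window smoothing length in windows (default 5).
#' @return smoothed BPM for the most recent window.
#' @export
smooth_output <- function(raw_history, window = 5L) {
  if (length(raw_history) == 0L) stop("empty estimate history")
  mean(utils::tail(raw_history, window))
}
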
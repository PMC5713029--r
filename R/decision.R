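# --- Per-window routing decisions -----------------------------------------

#' Detect motion artifacts from the acceleration spectra
#'
#' Motion artifacts are declared present when the in-band maximum PSD
#' amplitude of *every* acceleration axis exceeds `acc_amp_thresh`: genuine
#' wrist/arm motion shakes all three axes, whereas rest leaves at least one
#' axis quiet.
#'
#' @param acc_spectra list of three `nfeemd_spectrum` objects (x, y, z).
#' @param acc_amp_thresh PSD amplitude threshold (default 0.1); the scale
#'   follows [periodogram_spec()]'s normalization of mean-removed
#'   acceleration.
#' @param band search band in Hz.
#' @return logical flag: TRUE when artifacts are present.
#' @export
detect_motion <- function(acc_spectra, acc_amp_thresh = 0.1, band = c(0.5, 3)) {
  stopifnot(length(acc_spectra) == 3L)
  all(vapply(acc_spectra, function(s) {
    idx <- which(s$freqs >= band[1] & s$freqs <= band[2])
    length(idx) > 0L && max(s$power[idx]) > acc_amp_thresh
  }, logical(1)))
}

#' Is the acceleration data reliable for artifact-frequency extraction?
#'
#' A messy acceleration spectrum (too many comparable peaks on some axis)
#' cannot pinpoint the artifact frequencies. Reliability fails as soon as
#' any axis carries more than `th_acc_peaks` detected peaks.
#'
#' @param acc_peaksets list of three per-axis peak data frames
#'   (from [find_spec_peaks()]).
#' @param th_acc_peaks maximum tolerated peak count per axis (default 5).
#' @return logical flag: TRUE when every axis is reliable.
#' @export
acc_reliable <- function(acc_peaksets, th_acc_peaks = 5L) {
  stopifnot(length(acc_peaksets) == 3L)
  !any(vapply(acc_peaksets, nrow, integer(1)) > th_acc_peaks)
}

#' Remove PPG spectral peaks associated with acceleration peaks
#'
#' Drops every PPG peak whose BPM lies within `tol` (inclusive) of any
#' acceleration peak on any axis; those peaks are attributed to motion
#' rather than the heart beat. Order is preserved.
#'
#' @param ppg_peaks peak data frame of the (pre-processed) PPG window.
#' @param acc_peaksets list of three per-axis acceleration peak data frames.
#' @param tol matching tolerance in BPM (default 8, inclusive).
#' @return the surviving subset of `ppg_peaks`.
#' @export
remove_acc_peaks <- function(ppg_peaks, acc_peaksets, tol = 8) {
  stopifnot(tol > 0)
  acc_bpm <- unlist(lapply(acc_peaksets, function(p) p$bpm), use.names = FALSE)
  if (length(acc_bpm) == 0L || nrow(ppg_peaks) == 0L) return(ppg_peaks)
  keep <- vapply(ppg_peaks$bpm,
                 function(b) all(abs(b - acc_bpm) > tol), logical(1))
  ppg_peaks[keep, , drop = FALSE]
}

#' Route a motion-corrupted window to its processing case
#'
#' First ternary decision on the number of PPG peaks that survive
#' acceleration-peak removal: zero means the cardiac peak is masked
#' (`CASE3`, artifact-removal machinery, level-1 thresholds); exactly one
#' goes to the single-peak check (`CASE4`). With more than one survivor a
#' second ternary decision counts the peaks within `th_pass` BPM of the
#' previous estimate: zero again falls to `CASE3` (level-2 thresholds), one
#' to `CASE4` on that peak, several to `CASE5` (closest-peak selection).
#'
#' @param remaining peak data frame after [remove_acc_peaks()].
#' @param bpm_prev previous accepted estimate (BPM).
#' @param th_pass gating threshold in BPM (default 8).
#' @return list with `route` (`"CASE3"`, `"CASE4"` or `"CASE5"`), `level`
#'   (1 or 2: which ternary decision produced the route) and `peaks` (the
#'   peaks the case should consider).
#' @export
route_window <- function(remaining, bpm_prev, th_pass = 8) {
  n <- nrow(remaining)
  if (n == 0L) return(list(route = "CASE3", level = 1L, peaks = remaining))
  if (n == 1L) return(list(route = "CASE4", level = 1L, peaks = remaining))
  near <- remaining[abs(remaining$bpm - bpm_prev) <= th_pass, , drop = FALSE]
  if (nrow(near) == 0L) return(list(route = "CASE3", level = 2L, peaks = near))
  if (nrow(near) == 1L) return(list(route = "CASE4", level = 2L, peaks = near))
  list(route = "CASE5", level = 2L, peaks = near)
}
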
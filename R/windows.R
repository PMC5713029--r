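# --- Records and sliding analysis windows ---------------------------------

#' Construct a multichannel record
#'
#' @param ppg numeric PPG samples.
#' @param acc_x,acc_y,acc_z acceleration samples; all channels must share
#'   the PPG's length.
#' @param fs sampling rate in Hz (> 0).
#' @param truth_bpm optional per-window ground-truth BPM sequence.
#' @param id free-text label.
#' @return an `nfeemd_record`.
#' @export
new_record <- function(ppg, acc_x, acc_y, acc_z, fs,
                       truth_bpm = NULL, id = "") {
  chans <- list(ppg = as.numeric(ppg), acc_x = as.numeric(acc_x),
                acc_y = as.numeric(acc_y), acc_z = as.numeric(acc_z))
  lens <- vapply(chans, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have equal length (got ",
         paste(lens, collapse = ", "), ")")
  }
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (any(!vapply(chans, function(v) all(is.finite(v)), logical(1)))) {
    stop("record contains NaN/Inf samples; refusing to load")
  }
  structure(c(chans, list(fs = fs, truth_bpm = truth_bpm, id = id)),
            class = "nfeemd_record")
}

#' Slice a record into overlapping analysis windows
#'
#' Produces `floor((L - W)/S) + 1` windows of `W = round(win_seconds * fs)`
#' samples every `S = round(step_seconds * fs)` samples (defaults: 8-s
#' windows, 2-s step, i.e. 6 s overlap). Trailing samples that do not fill a
#' window are dropped. Windows are indexed from 0 and cover the half-open
#' sample range `[start_sample, start_sample + W)` (0-based).
#'
#' @param record an `nfeemd_record`.
#' @param win_seconds window length in seconds (default 8).
#' @param step_seconds stride in seconds (default 2).
#' @return list of `nfeemd_window` objects with fields `index`, `ppg`,
#'   `acc_x`, `acc_y`, `acc_z`, `fs`, `start_sample`.
#' @export
slide_windows <- function(record, win_seconds = 8, step_seconds = 2) {
  stopifnot(inherits(record, "nfeemd_record"))
  W <- round(win_seconds * record$fs)
  S <- round(step_seconds * record$fs)
  L <- length(record$ppg)
  if (L < W) stop("record (", L, " samples) shorter than one analysis window (",
                  W, " samples)")
  n_win <- (L - W) %/% S + 1L
  lapply(seq_len(n_win) - 1L, function(i) {
    sel <- (i * S + 1L):(i * S + W)
    structure(list(index = i, ppg = record$ppg[sel],
                   acc_x = record$acc_x[sel], acc_y = record$acc_y[sel],
                   acc_z = record$acc_z[sel],
                   fs = record$fs, start_sample = i * S),
              class = "nfeemd_window")
  })
}
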
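#' Run the full heart-rate estimation pipeline on a record
#'
#' Orchestrates windowing, motion-artifact detection, per-window routing,
#' notch/decomposition recovery, tracking, calibration and output
#' smoothing:
#'
#' 1. **Initialization** — windows are scanned until the raw PPG
#'    periodogram shows exactly one in-band 30%-peak; earlier windows are
#'    reported as NA.
#' 2. **Motion detection** — artifacts are present when every acceleration
#'    axis has in-band PSD amplitude above the threshold.
#' 3. **No artifacts** — the highest spectral peak of the band-passed PPG
#'    is gated against the previous estimate (`th_pass`); after two
#'    consecutive fallbacks the first calibration re-estimates from the raw
#'    periodogram and escapes a stuck value when the new peak is far away.
#' 4. **Artifacts present** — unreliable acceleration (too many peaks on an
#'    axis) keeps the past value. Otherwise acceleration-matched PPG peaks
#'    are removed and two ternary decisions route the window: masked peak
#'    (notch cascade, then EEMD+SSA), single survivor, or closest-of-many.
#' 5. **Second calibration** — when the window fell back while artifacts
#'    are present, and either the grey-model forecast of the recent
#'    estimates disagrees with the held value by more than
#'    `calib2_pred_gap` or three consecutive fallbacks have accumulated,
#'    the heart rate is re-estimated through the notch cascade and accepted
#'    within `calib2_accept`.
#' 6. **Smoothing** — the reported series is a moving average of the last
#'    `smooth_window` raw estimates.
#'
#' @param record an `nfeemd_record`.
#' @param cfg a [tracker_config()].
#' @param seed integer seed controlling the (per-window derived) ensemble
#'   decomposition noise; fixed seed gives bit-identical output.
#' @param trace when TRUE a per-window decision trace is attached as
#'   attribute `"trace"` (window index, motion flag, reliability flag,
#'   route, method, acceptance).
#' @return data frame with one row per window: `window_index`, `time_s`,
#'   `bpm_raw`, `bpm_est` (smoothed), `route`, `method`, `accepted`, and
#'   `bpm_true` when the record carries ground truth. Pre-initialization
#'   windows have NA estimates and route `"INIT"`.
#' @export
run_pipeline <- function(record, cfg = tracker_config(), seed = 1L,
                         trace = FALSE) {
  stopifnot(inherits(record, "nfeemd_record"))
  windows <- slide_windows(record, cfg$win_seconds, cfg$step_seconds)
  init <- initialize_tracker(windows, cfg)
  n_win <- length(windows)
  out <- data.frame(window_index = vapply(windows, `[[`, integer(1), "index"),
                    time_s = NA_real_, bpm_raw = NA_real_,
                    bpm_est = NA_real_, route = "INIT", method = "",
                    accepted = NA)
  out$time_s <- out$window_index * cfg$step_seconds

  bpm_prev <- init$bpm
  raw_history <- init$bpm
  fallback_noma <- 0L
  fallback_ma <- 0L
  i0 <- init$index + 1L  # 1-based row of the init window
  out$bpm_raw[i0] <- init$bpm
  out$bpm_est[i0] <- init$bpm
  out$route[i0] <- "INIT_ACCEPT"
  out$method[i0] <- "RAW_PEAK"
  out$accepted[i0] <- TRUE

  for (i in seq_len(n_win)) {
    if (i <= i0) next
    w <- windows[[i]]
    acc_spectra <- lapply(list(w$acc_x, w$acc_y, w$acc_z),
                          periodogram_spec, fs = w$fs, nfft = cfg$nfft)
    ma <- detect_motion(acc_spectra, cfg$acc_amp_thresh, cfg$band)
    route <- NA_character_
    method <- ""
    res <- NULL
    acc_peaksets <- NULL

    if (!ma) {
      if (fallback_noma >= 2L) {
        # Calibration 1: re-estimate from the raw periodogram; a nearby
        # peak keeps the held value, a distant one escapes it.
        cand <- top_peak_bpm(w$ppg, w$fs, cfg)
        if (is.finite(cand) && abs(cand - bpm_prev) > cfg$th_pass) {
          res <- list(bpm = cand, accepted = TRUE)
        } else {
          res <- list(bpm = bpm_prev, accepted = FALSE)
        }
        route <- "CASE1"; method <- "CALIB1"
      } else {
        pre <- bandpass_mavg(w$ppg, w$fs, cfg$band[1], cfg$band[2])
        cand <- top_peak_bpm(pre, w$fs, cfg)
        res <- if (is.finite(cand) && abs(cand - bpm_prev) <= cfg$th_pass) {
          list(bpm = cand, accepted = TRUE)
        } else {
          list(bpm = bpm_prev, accepted = FALSE)
        }
        route <- "CASE1"; method <- "PRE_PEAK"
      }
    } else {
      acc_peaksets <- lapply(acc_spectra, find_spec_peaks,
                             rel_thresh = cfg$rel_thresh, band = cfg$band)
      if (!acc_reliable(acc_peaksets, cfg$th_acc_peaks)) {
        res <- list(bpm = bpm_prev, accepted = FALSE)
        route <- "CASE2"; method <- "FALLBACK"
      } else {
        pre <- bandpass_mavg(w$ppg, w$fs, cfg$band[1], cfg$band[2])
        pre_spec <- periodogram_spec(pre, w$fs, nfft = cfg$nfft)
        ppg_peaks <- find_spec_peaks(pre_spec, cfg$rel_thresh, cfg$band)
        remaining <- remove_acc_peaks(ppg_peaks, acc_peaksets,
                                      cfg$peak_match_tol)
        routed <- route_window(remaining, bpm_prev, cfg$th_pass)
        route <- routed$route
        if (routed$route == "CASE3") {
          res <- case3_estimate(w, bpm_prev, routed$level, acc_peaksets, cfg,
                                eemd_seed = seed + w$index)
          method <- res$method
        } else if (routed$route == "CASE4") {
          res <- gate_strict(routed$peaks$bpm[1L], bpm_prev, cfg$th_pass)
          method <- "SINGLE_PEAK"
        } else {  # CASE5: closest surviving peak, ties toward the lower BPM
          pk <- routed$peaks
          ord <- order(abs(pk$bpm - bpm_prev), pk$bpm)
          res <- gate_strict(pk$bpm[ord[1L]], bpm_prev, cfg$th_pass)
          method <- "CLOSEST_PEAK"
        }
      }
    }

    # Calibration 2: only meaningful while artifacts persist and the
    # current window fell back on the past value.
    if (ma && cfg$use_calibration2 && !res$accepted) {
      trig_count <- fallback_ma + 1L >= 3L
      trig_gm <- FALSE
      hist <- utils::tail(raw_history, cfg$gm_history)
      if (length(hist) >= 4L) {
        pred <- tryCatch(gm11_predict(hist), error = function(e) NA_real_)
        trig_gm <- is.finite(pred) &&
          abs(pred - bpm_prev) > cfg$calib2_pred_gap
      }
      if (trig_count || trig_gm) {
        if (is.null(acc_peaksets)) {
          acc_peaksets <- lapply(acc_spectra, find_spec_peaks,
                                 rel_thresh = cfg$rel_thresh,
                                 band = cfg$band)
        }
        ma_freqs <- unique(unlist(lapply(acc_peaksets, function(p) p$freq),
                                  use.names = FALSE))
        notched <- repeated_notch(w$ppg, ma_freqs, w$fs, r = cfg$notch_r,
                                  max_notches = cfg$max_notches,
                                  acc_peaksets = acc_peaksets)
        cand <- top_peak_bpm(notched, w$fs, cfg)
        if (is.finite(cand) && abs(cand - bpm_prev) < cfg$calib2_accept) {
          res <- list(bpm = cand, accepted = TRUE)
          method <- "CALIB2"
        }
      }
    }

    if (res$accepted) {
      fallback_noma <- 0L
      fallback_ma <- 0L
    } else if (ma) {
      fallback_ma <- fallback_ma + 1L
    } else {
      fallback_noma <- fallback_noma + 1L
    }
    raw_history <- c(raw_history, res$bpm)
    bpm_prev <- res$bpm
    out$bpm_raw[i] <- res$bpm
    out$bpm_est[i] <- smooth_output(raw_history, cfg$smooth_window)
    out$route[i] <- route
    out$method[i] <- method
    out$accepted[i] <- res$accepted
  }

  if (!is.null(record$truth_bpm)) {
    tb <- rep(NA_real_, n_win)
    k <- min(n_win, length(record$truth_bpm))
    tb[seq_len(k)] <- record$truth_bpm[seq_len(k)]
    out$bpm_true <- tb
  }
  if (trace) {
    attr(out, "trace") <- out[, c("window_index", "route", "method",
                                  "accepted")]
  }
  out
}

#' Evaluate a pipeline result against its ground truth
#'
#' Convenience wrapper computing the agreement report
#' ([hr_aae()], [hr_aep()], [hr_bland_altman()], [hr_pearson()]) on the
#' post-initialization windows of a [run_pipeline()] result that carry
#' truth values.
#'
#' @param result data frame from [run_pipeline()] with a `bpm_true` column.
#' @return a `metrics_report` list (see [hr_bland_altman()]); also reports
#'   `n_windows` used and `n_discarded` (pre-initialization windows).
#' @export
evaluate_result <- function(result) {
  if (is.null(result$bpm_true)) stop("result has no ground truth attached")
  ok <- is.finite(result$bpm_est) & is.finite(result$bpm_true)
  est <- result$bpm_est[ok]
  truth <- result$bpm_true[ok]
  ba <- hr_bland_altman(est, truth)
  pr <- hr_pearson(est, truth)
  structure(list(aae = hr_aae(est, truth), aep = hr_aep(est, truth),
                 mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                 loa = ba$loa, within_loa = ba$within_loa,
                 pearson_r = pr$r, slope = pr$slope,
                 intercept = pr$intercept,
                 n_windows = sum(ok), n_discarded = sum(!ok)),
            class = "metrics_report")
}
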
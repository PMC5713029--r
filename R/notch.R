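#' Design a second-order IIR single-notch filter
#'
#' Transfer function with a zero pair on the unit circle at the notch
#' frequency and a pole pair at radius `r` just inside it:
#' \deqn{H(z) = \frac{1 - 2\cos(w_0) z^{-1} + z^{-2}}
#'             {1 - 2 r \cos(w_0) z^{-1} + r^2 z^{-2}}}
#' with `w0 = 2*pi*f0/fs`. The gain at `f0` is exactly zero; `r` (default
#' 0.96) sets the notch bandwidth, roughly `fs * (1 - r) / pi` Hz at -3 dB.
#'
#' @param f0 notch frequency in Hz, `0 < f0 < fs/2`.
#' @param fs sampling rate (Hz).
#' @param r pole radius in (0, 1).
#' @return an `nfeemd_notch`: list with `f0`, `fs`, `r`, `w0` and coefficient
#'   vectors `b` (numerator) and `a` (denominator).
#' @export
design_notch <- function(f0, fs, r = 0.96) {
  if (!is.finite(f0) || f0 <= 0 || f0 >= fs / 2) {
    stop("notch frequency must lie strictly inside (0, fs/2)")
  }
  if (r < 0 || r >= 1) stop("pole radius r must be in [0, 1)")
  w0 <- 2 * pi * f0 / fs
  structure(
    list(f0 = f0, fs = fs, r = r, w0 = w0,
         b = c(1, -2 * cos(w0), 1),
         a = c(1, -2 * r * cos(w0), r^2)),
    class = "nfeemd_notch"
  )
}

#' Frequency response magnitude of a notch filter
#'
#' Evaluates `|H(e^{j 2 pi f / fs})|` from the designed coefficients.
#'
#' @param spec an `nfeemd_notch`.
#' @param f frequencies in Hz (vectorised).
#' @return magnitude response at `f`.
#' @export
notch_gain <- function(spec, f) {
  w <- 2 * pi * f / spec$fs
  z1 <- exp(-1i * w)
  num <- spec$b[1] + spec$b[2] * z1 + spec$b[3] * z1^2
  den <- spec$a[1] + spec$a[2] * z1 + spec$a[3] * z1^2
  Mod(num / den)
}

#' Apply a single-notch filter to a signal
#'
#' Direct-form IIR filtering with zero initial state (single causal pass).
#' The startup transient decays with time constant about `1/(fs*(1-r))`
#' seconds, short relative to an 8-s analysis window at the default
#' `r = 0.96`.
#'
#' @param x numeric samples (length >= 3).
#' @param spec an `nfeemd_notch` from [design_notch()].
#' @return filtered samples, same length.
#' @export
apply_notch <- function(x, spec) {
  stopifnot(inherits(spec, "nfeemd_notch"))
  if (length(x) < 3L) stop("signal too short to notch-filter")
  as.numeric(signal::filter(spec$b, spec$a, as.numeric(x)))
}

# Largest-amplitude peak frequency per acceleration axis (Hz), ties toward
# the lower frequency; axes without peaks are dropped.
top_freq_per_axis <- function(acc_peaksets) {
  out <- numeric(0)
  for (pk in acc_peaksets) {
    if (is.null(pk) || nrow(pk) == 0L) next
    best <- pk[order(-pk$amplitude, pk$freq), , drop = FALSE]
    out <- c(out, best$freq[1L])
  }
  unique(out)
}

#' Cascade of single-notch filters at the motion-artifact frequencies
#'
#' Applies one notch per distinct artifact frequency when there are at most
#' `max_notches` of them. When more frequencies are detected, only the
#' largest-amplitude peak of each acceleration axis is notched (at most
#' three), so that the cardiac component of the signal is disturbed as
#' little as possible.
#'
#' @param x raw PPG samples of one analysis window.
#' @param ma_freqs numeric vector of artifact frequencies (Hz); duplicates
#'   count once.
#' @param fs sampling rate (Hz).
#' @param r pole radius (default 0.96).
#' @param max_notches cascade depth cap (default 3).
#' @param acc_peaksets optional list of three per-axis peak `data.frame`s
#'   (from [find_spec_peaks()]); required to pick per-axis top peaks when
#'   `length(ma_freqs) > max_notches`.
#' @return filtered samples; `x` unchanged when `ma_freqs` is empty.
#' @export
repeated_notch <- function(x, ma_freqs, fs, r = 0.96, max_notches = 3L,
                           acc_peaksets = NULL) {
  freqs <- unique(as.numeric(ma_freqs))
  freqs <- freqs[is.finite(freqs) & freqs > 0 & freqs < fs / 2]
  if (length(freqs) == 0L) return(as.numeric(x))
  if (length(freqs) > max_notches) {
    if (!is.null(acc_peaksets)) {
      freqs <- top_freq_per_axis(acc_peaksets)
    }
    freqs <- utils::head(freqs, max_notches)
  }
  y <- as.numeric(x)
  for (f0 in freqs) y <- apply_notch(y, design_notch(f0, fs, r))
  y
}
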
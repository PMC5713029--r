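#' One-sided periodogram of a signal window
#'
#' Computes the rectangular-window periodogram used throughout the pipeline:
#' the signal is (optionally) mean-removed, zero-padded to `nfft` points, and
#' the squared FFT magnitude is scaled to a one-sided power spectral density,
#' `|X(k)|^2 / (N * fs)` with interior bins doubled. With this convention the
#' integral of the PSD over frequency equals the time-domain mean square of
#' the (demeaned) signal.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param nfft FFT length; must be at least `length(x)`. Default 4096.
#' @param demean subtract the sample mean before transforming (default TRUE);
#'   zero-padding a signal with a DC offset would otherwise smear leakage
#'   across the whole band.
#' @return an object of class `nfeemd_spectrum`: a list with `freqs` (Hz, one
#'   per bin `0..nfft/2`), `power` (PSD, a.u.^2/Hz), `nfft`, `fs` and `n`
#'   (the original signal length). Bin `k` (0-based) sits at `k * fs / nfft`.
#' @export
periodogram_spec <- function(x, fs, nfft = 4096, demean = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("periodogram requires at least 2 samples")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (nfft < n) stop("nfft (", nfft, ") must be >= signal length (", n, ")")
  if (demean) x <- x - mean(x)
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  half <- nfft %/% 2L
  p <- (Mod(xf[seq_len(half + 1L)])^2) / (n * fs)
  if (half >= 2L) p[2:half] <- 2 * p[2:half]
  structure(
    list(freqs = (0:half) * fs / nfft, power = p, nfft = nfft, fs = fs, n = n),
    class = "nfeemd_spectrum"
  )
}

#' Convert an FFT bin index to beats per minute
#'
#' @param bin 0-based bin index (vectorised), `0 <= bin <= nfft/2`.
#' @param fs sampling rate (Hz).
#' @param nfft FFT length.
#' @return BPM value(s): `60 * bin * fs / nfft`.
#' @export
bpm_of_bin <- function(bin, fs, nfft) {
  if (any(bin < 0) || any(bin > nfft / 2)) {
    stop("bin index out of range [0, nfft/2]")
  }
  60 * bin * fs / nfft
}

# Strict local maxima of a numeric vector, plateau runs collapsed to their
# first index. Endpoints are never maxima.
local_maxima <- function(p) {
  r <- rle(p)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_max <- logical(k)
  for (j in 2:(k - 1L)) {
    is_max[j] <- r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]
  }
  starts[is_max]
}

#' Detect spectral peaks above a relative amplitude threshold
#'
#' Local maxima of the periodogram inside a frequency band are kept when their
#' amplitude exceeds `rel_thresh` times the band maximum (the 30% rule used
#' by every decision stage). A spectrum with no strict local maximum in the
#' band but non-zero power degenerates to the single band-maximum bin; an
#' all-zero band yields an empty peak set.
#'
#' @param spec an `nfeemd_spectrum`.
#' @param rel_thresh fraction of the in-band maximum amplitude (default 0.30).
#' @param band numeric length-2, search band in Hz (default `c(0.5, 3)`,
#'   i.e. 30-180 BPM).
#' @return a `data.frame` with columns `freq` (Hz), `bpm`, `amplitude`, `bin`
#'   (0-based), sorted by descending amplitude.
#' @export
find_spec_peaks <- function(spec, rel_thresh = 0.30, band = c(0.5, 3)) {
  stopifnot(inherits(spec, "nfeemd_spectrum"), length(band) == 2L)
  if (band[2] > spec$fs / 2) stop("band exceeds the Nyquist frequency")
  in_band <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  empty <- data.frame(freq = numeric(0), bpm = numeric(0),
                      amplitude = numeric(0), bin = integer(0))
  if (length(in_band) == 0L) return(empty)
  band_max <- max(spec$power[in_band])
  if (band_max <= 0) return(empty)
  idx <- local_maxima(spec$power)
  idx <- intersect(idx, in_band)
  idx <- idx[spec$power[idx] > rel_thresh * band_max]
  if (length(idx) == 0L) idx <- in_band[which.max(spec$power[in_band])]
  idx <- idx[order(spec$power[idx], decreasing = TRUE)]
  bins <- idx - 1L  # 0-based
  data.frame(
    freq = spec$freqs[idx],
    bpm = bpm_of_bin(bins, spec$fs, spec$nfft),
    amplitude = spec$power[idx],
    bin = bins
  )
}

# Highest-amplitude in-band peak of a signal, as BPM; NA when the band is
# silent. Convenience used by the tracker.
top_peak_bpm <- function(x, fs, cfg) {
  spec <- periodogram_spec(x, fs, nfft = cfg$nfft)
  pk <- find_spec_peaks(spec, rel_thresh = cfg$rel_thresh, band = cfg$band)
  if (nrow(pk) == 0L) return(NA_real_)
  pk$bpm[1L]
}
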
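# Centered moving average with reflection padding; exact via cumulative sums.
moving_average <- function(x, m) {
  n <- length(x)
  if (m <= 1L) return(x)
  if (m >= n) stop("moving-average window (", m, ") too long for signal (", n, ")")
  left <- (m - 1L) %/% 2L
  right <- m - 1L - left
  xp <- c(rev(x[seq_len(left) + 1L]), x, rev(x[(n - right):(n - 1L)]))
  cs <- cumsum(c(0, xp))
  (cs[(m + 1L):(m + n)] - cs[seq_len(n)]) / m
}

#' Band-limit a raw PPG signal with repeated moving averages
#'
#' The physiological band (default 0.5-3 Hz, 30-180 BPM) is isolated with a
#' cascade of moving-average stages: a repeated short moving average acts as
#' the low-pass, and a repeated long moving average estimates the baseline
#' trend which is subtracted (high-pass). All stages are centered (zero
#' phase) with reflection padding, so the output has the same length as the
#' input and the DC component is removed exactly.
#'
#' The low-pass length is `round(fs / (2 * high))`, placing its first null at
#' twice the upper band edge so the mid-band gain stays near unity; the
#' trend length is `round(fs / low)`, placing its first null at the lower
#' band edge (full transmission at the edge, attenuation below).
#'
#' @param x numeric samples.
#' @param fs sampling rate (Hz); must exceed `2 * high`.
#' @param low,high band edges in Hz (defaults 0.5 and 3).
#' @param repeats number of passes of each moving-average stage (default 2).
#' @return filtered samples, same length as `x`.
#' @export
bandpass_mavg <- function(x, fs, low = 0.5, high = 3.0, repeats = 2L) {
  x <- as.numeric(x)
  if (fs <= 2 * high) stop("fs must exceed twice the upper band edge")
  m_lp <- max(2L, round(fs / (2 * high)))
  m_hp <- max(2L, round(fs / low))
  if (length(x) <= m_hp) {
    stop("signal (", length(x), " samples) too short for the ",
         m_hp, "-sample trend window")
  }
  y <- x
  for (i in seq_len(repeats)) y <- moving_average(y, m_lp)
  trend <- y
  for (i in seq_len(repeats)) trend <- moving_average(trend, m_hp)
  y - trend
}
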
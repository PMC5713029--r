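#' Rank-1 singular spectrum analysis reconstruction
#'
#' Embeds the series in an `L x (N-L+1)` Hankel trajectory matrix, keeps the
#' leading singular triple, and reconstructs a series of the original length
#' by anti-diagonal averaging. This retains the single most principal
#' oscillatory/trend component and strictly reduces the energy of anything
#' that is not rank-1 in the embedding.
#'
#' @param x numeric samples, length `N > L`.
#' @param L embedding window length (default 150 samples); values `>= N` are
#'   an error.
#' @return denoised samples of length `N`.
#' @export
ssa_rank1 <- function(x, L = 150L) {
  x <- as.numeric(x)
  n <- length(x)
  if (L < 2L) stop("SSA window length must be >= 2")
  if (n <= L) stop("signal length (", n, ") must exceed the SSA window (", L, ")")
  K <- n - L + 1L
  X <- matrix(x[outer(seq_len(L), 0:(K - 1L), `+`)], nrow = L, ncol = K)
  sv <- svd(X, nu = 1L, nv = 1L)
  u <- sv$u[, 1L] * sv$d[1L]
  v <- sv$v[, 1L]
  # anti-diagonal sums of the rank-1 matrix u v^T via open convolution
  sums <- stats::convolve(u, rev(v), type = "open")
  counts <- pmin(seq_len(n), L, K, n - seq_len(n) + 1L)
  sums / counts
}

#' Dominant cycle of an IMF, in beats per minute
#'
#' The dominant periodogram frequency of the component (DC excluded) is
#' converted to BPM. An effectively silent component has no defined cycle
#' and returns `NA`.
#'
#' @param imf numeric samples.
#' @param fs sampling rate (Hz).
#' @param nfft FFT length (default 4096).
#' @return BPM, or `NA_real_` for a silent component.
#' @export
estimate_cycle <- function(imf, fs, nfft = 4096) {
  imf <- as.numeric(imf)
  if (length(imf) < 2L || all(abs(imf - mean(imf)) < 1e-12)) return(NA_real_)
  spec <- periodogram_spec(imf, fs, nfft = max(nfft, length(imf)))
  k <- which.max(spec$power[-1L])  # skip DC bin
  bpm_of_bin(k, fs, spec$nfft)
}

#' Select the IMF whose cycle is closest to the previous heart rate
#'
#' Each IMF is first denoised with rank-1 SSA, its dominant cycle estimated,
#' and the component minimizing `|cycle - bpm_prev|` is returned. Ties break
#' toward the lower-index (higher-frequency) IMF.
#'
#' @param imfset an `nfeemd_imfset` from [emd()] or [eemd()].
#' @param bpm_prev previous accepted heart-rate estimate (BPM).
#' @param fs sampling rate (Hz).
#' @param ssa_L SSA embedding length (default 150); reduced automatically
#'   for short components.
#' @param nfft FFT length for cycle estimation.
#' @return list with `signal` (the SSA-denoised selected IMF), `cycle`
#'   (its BPM) and `index` (1-based IMF index).
#' @export
select_imf <- function(imfset, bpm_prev, fs, ssa_L = 150L, nfft = 4096) {
  stopifnot(inherits(imfset, "nfeemd_imfset"))
  if (length(imfset$imfs) == 0L) {
    stop("empirical mode decomposition produced no usable component")
  }
  cand <- vector("list", length(imfset$imfs))
  cycles <- rep(NA_real_, length(imfset$imfs))
  for (j in seq_along(imfset$imfs)) {
    imf <- imfset$imfs[[j]]
    L <- min(ssa_L, max(2L, length(imf) %/% 2L))
    den <- ssa_rank1(imf, L = L)
    cand[[j]] <- den
    cycles[j] <- estimate_cycle(den, fs, nfft = nfft)
  }
  ok <- which(is.finite(cycles))
  if (length(ok) == 0L) {
    stop("empirical mode decomposition produced no usable component")
  }
  best <- ok[which.min(abs(cycles[ok] - bpm_prev))]
  list(signal = cand[[best]], cycle = cycles[best], index = best)
}
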
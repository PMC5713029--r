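# --- Empirical mode decomposition (sifting with cubic-spline envelopes) ----
#
# Hand-rolled on purpose: the decomposition, its mirror boundary treatment
# and the ensemble variant below are the core of the artifact-removal
# method, and the exact sifting behaviour matters to the tests.

# Indices of strict local maxima / minima; plateaus collapse to their first
# sample (sign of the difference carried across zero runs).
find_extrema <- function(x) {
  d <- diff(x)
  nz <- d != 0
  if (!any(nz)) return(list(max = integer(0), min = integer(0)))
  # carry the last non-zero slope over flat runs
  s <- sign(d)
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- last else last <- s[i]
  }
  ds <- diff(s)
  imax <- which(ds < 0) + 1L
  imin <- which(ds > 0) + 1L
  list(max = imax, min = imin)
}

# Upper/lower cubic-spline envelopes with mirror extension of up to `nmir`
# extrema on each side (reflected about the end samples) to tame end
# effects.
envelope_mean <- function(x, ext, nmir = 2L) {
  n <- length(x)
  mirror <- function(idx, val) {
    k <- length(idx)
    lm <- min(nmir, k)
    ti <- c(2 - rev(idx[seq_len(lm)]), idx, 2 * n - rev(idx[(k - lm + 1L):k]))
    vi <- c(rev(val[seq_len(lm)]), val, rev(val[(k - lm + 1L):k]))
    keep <- !duplicated(ti)
    list(t = ti[keep], v = vi[keep])
  }
  up <- mirror(ext$max, x[ext$max])
  lo <- mirror(ext$min, x[ext$min])
  eu <- stats::spline(up$t, up$v, xout = seq_len(n), method = "fmm")$y
  el <- stats::spline(lo$t, lo$v, xout = seq_len(n), method = "fmm")$y
  (eu + el) / 2
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

imf_condition_ok <- function(x) {
  ext <- find_extrema(x)
  abs(length(ext$max) + length(ext$min) - count_zero_crossings(x)) <= 1L
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by sifting:
#' cubic-spline envelopes are fitted through the local maxima and minima
#' (with mirror extension of the end extrema), their mean is subtracted, and
#' the process repeats until the candidate satisfies the IMF conditions
#' (extrema and zero-crossing counts differing by at most one) and the
#' normalized squared difference between successive sifts drops below
#' `sift_tol`. Extraction stops when the residual has fewer than two maxima
#' or two minima (monotone trend). The components telescope, so
#' `Reduce("+", imfs) + residue` reproduces the input to machine precision.
#'
#' @param x numeric samples (length >= 8), finite.
#' @param max_sift cap on sifting iterations per IMF (default 200; convergence of the mode conditions occasionally needs well over 50 sifts).
#' @param sift_tol stopping threshold on the normalized squared difference
#'   between successive sifts (default 0.2).
#' @param max_imf cap on the number of IMFs (default 16).
#' @return an `nfeemd_imfset`: list with `imfs` (list of numeric vectors,
#'   highest frequency first), `residue`, and `n_sift` (iterations used per
#'   IMF).
#' @export
emd <- function(x, max_sift = 200L, sift_tol = 0.2, max_imf = 16L) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop("signal too short for EMD")
  if (!all(is.finite(x))) stop("EMD input must be finite")
  residual <- x
  imfs <- list()
  n_sift <- integer(0)
  while (length(imfs) < max_imf) {
    ext <- find_extrema(residual)
    if (length(ext$max) < 2L || length(ext$min) < 2L) break
    h <- residual
    sifts <- 0L
    repeat {
      exth <- find_extrema(h)
      if (length(exth$max) < 2L || length(exth$min) < 2L) break
      m <- envelope_mean(h, exth)
      h1 <- h - m
      sifts <- sifts + 1L
      denom <- sum(h^2)
      sd_crit <- if (denom > 0) sum((h - h1)^2) / denom else 0
      h <- h1
      if ((sd_crit < sift_tol && imf_condition_ok(h)) || sifts >= max_sift) break
    }
    imfs[[length(imfs) + 1L]] <- h
    n_sift <- c(n_sift, sifts)
    residual <- residual - h
  }
  structure(list(imfs = imfs, residue = residual, n_sift = n_sift),
            class = "nfeemd_imfset")
}

# Evaluate a block with a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `ne` copies of the signal perturbed with white Gaussian
#' noise of standard deviation `noise_sd_ratio * sd(x)` and averages the
#' IMFs across the ensemble, index by index (members with fewer IMFs are
#' padded with zeros). The added noise populates the whole time-frequency
#' plane, which weakens mode mixing. With `noise_sd_ratio = 0` the result
#' equals a plain [emd()]. Fully deterministic for a given `seed`.
#'
#' @param x numeric samples.
#' @param ne ensemble size (default 5).
#' @param noise_sd_ratio noise standard deviation as a fraction of `sd(x)`
#'   (default 0.05).
#' @param seed integer RNG seed; the caller's RNG state is preserved.
#' @inheritParams emd
#' @return an `nfeemd_imfset` of ensemble-averaged IMFs and residue.
#' @export
eemd <- function(x, ne = 5L, noise_sd_ratio = 0.05, seed = NULL,
                 max_sift = 200L, sift_tol = 0.2, max_imf = 16L) {
  x <- as.numeric(x)
  if (ne < 1L) stop("ensemble size must be >= 1")
  sigma <- noise_sd_ratio * stats::sd(x)
  if (!is.finite(sigma)) sigma <- 0
  with_local_seed(seed, {
    members <- vector("list", ne)
    for (p in seq_len(ne)) {
      noisy <- x + stats::rnorm(length(x), 0, sigma)
      members[[p]] <- emd(noisy, max_sift = max_sift, sift_tol = sift_tol,
                          max_imf = max_imf)
    }
    n_imf <- max(vapply(members, function(m) length(m$imfs), integer(1)))
    zero <- rep(0, length(x))
    imfs <- vector("list", n_imf)
    for (j in seq_len(n_imf)) {
      acc <- zero
      for (p in seq_len(ne)) {
        cj <- if (j <= length(members[[p]]$imfs)) members[[p]]$imfs[[j]] else zero
        acc <- acc + cj
      }
      imfs[[j]] <- acc / ne
    }
    res <- Reduce(`+`, lapply(members, `[[`, "residue")) / ne
    structure(list(imfs = imfs, residue = res,
                   n_sift = members[[1L]]$n_sift),
              class = "nfeemd_imfset")
  })
}
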
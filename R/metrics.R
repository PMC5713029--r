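# --- Agreement metrics -----------------------------------------------------

#' Average absolute error of a heart-rate series
#'
#' `AAE = mean(|est - truth|)` in BPM.
#'
#' @param est,truth equal-length numeric series (BPM).
#' @return AAE in BPM.
#' @export
hr_aae <- function(est, truth) {
  if (length(est) != length(truth)) stop("series lengths differ")
  if (length(est) < 1L) stop("empty series")
  mean(abs(est - truth))
}

#' Average absolute error percentage
#'
#' `AEP = mean(|est - truth| / truth) * 100`; the denominator is the
#' ground truth, so the measure is not symmetric in its arguments.
#'
#' @param est,truth equal-length numeric series; `truth` strictly positive.
#' @return AEP in percent.
#' @export
hr_aep <- function(est, truth) {
  if (length(est) != length(truth)) stop("series lengths differ")
  if (any(truth <= 0)) stop("truth values must be strictly positive")
  mean(abs(est - truth) / truth) * 100
}

#' Bland-Altman agreement of two heart-rate series
#'
#' Differences `d = est - truth` summarized by their mean, sample (n-1)
#' standard deviation and the limits of agreement
#' `[mean - 1.96 sd, mean + 1.96 sd]`, plus the fraction of differences
#' falling inside them.
#'
#' @param est,truth equal-length numeric series, `N >= 2`.
#' @return list with `mean_diff`, `sd_diff`, `loa` (length-2), `within_loa`
#'   (fraction), and `differences`.
#' @export
hr_bland_altman <- function(est, truth) {
  if (length(est) != length(truth)) stop("series lengths differ")
  if (length(est) < 2L) stop("need at least 2 paired values")
  d <- est - truth
  mu <- mean(d)
  sdd <- stats::sd(d)
  loa <- c(mu - 1.96 * sdd, mu + 1.96 * sdd)
  list(mean_diff = mu, sd_diff = sdd, loa = loa,
       within_loa = mean(d >= loa[1] & d <= loa[2]),
       differences = d)
}

#' Pearson correlation and fitted line of estimate on truth
#'
#' @param est,truth equal-length non-constant numeric series, `N >= 2`.
#' @return list with `r`, `slope`, `intercept` (least-squares fit of `est`
#'   on `truth`).
#' @export
hr_pearson <- function(est, truth) {
  if (length(est) != length(truth)) stop("series lengths differ")
  if (length(est) < 2L) stop("need at least 2 paired values")
  if (stats::sd(est) == 0 || stats::sd(truth) == 0) {
    stop("correlation undefined for a constant series")
  }
  fit <- stats::lm(est ~ truth)
  list(r = stats::cor(est, truth),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]))
}
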
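#' One-step-ahead grey-model GM(1,1) forecast
#'
#' Classical first-order grey prediction: the positive series is cumulated,
#' the whitening equation `x0(k) = -a * z(k) + b` (with `z` the consecutive
#' means of the cumulated series) is fitted by least squares, and the next
#' term of the original series is forecast from the fitted exponential. The
#' model is exact on geometric series and degenerates gracefully to the
#' constant for `a -> 0`.
#'
#' @param x positive numeric series, length >= 4.
#' @return the forecast of the next term (one step ahead).
#' @export
gm11_predict <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("GM(1,1) needs at least 4 values")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("GM(1,1) requires a strictly positive series")
  }
  x1 <- cumsum(x)
  z <- 0.5 * (x1[-1L] + x1[-n])
  B <- cbind(-z, 1)
  Y <- x[-1L]
  theta <- tryCatch(solve(crossprod(B), crossprod(B, Y)),
                    error = function(e) NULL)
  if (is.null(theta)) return(x[n])
  a <- theta[1L]
  b <- theta[2L]
  if (abs(a) < 1e-10) return(b)
  # x1_hat(k+1) = (x(1) - b/a) exp(-a k) + b/a, k = 0-based
  (x[1L] - b / a) * (1 - exp(a)) * exp(-a * n)
}
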
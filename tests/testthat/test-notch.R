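test_that("notch coefficients realize a true spectral zero", {
  sp <- design_notch(2.87, 125)
  expect_equal(sp$b, c(1, -2 * cos(sp$w0), 1))
  expect_equal(sp$a, c(1, -2 * 0.96 * cos(sp$w0), 0.96^2))
  expect_lt(notch_gain(sp, 2.87), 1e-12)
  # DC gain matches the closed form (2 - 2 cos w0) / (1 - 2 r cos w0 + r^2)
  dc <- (2 - 2 * cos(sp$w0)) / (1 - 2 * 0.96 * cos(sp$w0) + 0.96^2)
  expect_equal(notch_gain(sp, 0), dc, tolerance = 1e-12)
  # r -> 0: denominator collapses to 1 (pure FIR notch)
  sp0 <- design_notch(2.87, 125, r = 0)
  expect_equal(sp0$a, c(1, 0, 0))
  expect_error(design_notch(0, 125), "inside")
  expect_error(design_notch(70, 125), "inside")
})

test_that("filtering suppresses the notch frequency far more than neighbours", {
  fs <- 125; t <- (0:1999) / fs
  sp <- design_notch(2.87, fs)
  post <- 251:2000  # discard the 2-s startup transient
  rms <- function(x) sqrt(mean(x^2))
  at <- rms(apply_notch(tone(2.87, t), sp)[post])
  off <- rms(apply_notch(tone(2.37, t), sp)[post])
  expect_lt(at, 0.05)          # residual under 5% of unit input
  expect_lt(at / off, 0.2)     # selective: 0.5 Hz away survives
  expect_equal(apply_notch(rep(0, 100), sp), rep(0, 100))
})

test_that("the cascade caps at three notches, deduplicates, and commutes", {
  fs <- 125; t <- (0:999) / fs
  x <- tone(2.72, t) + tone(1.43, t, 4) + tone(2.87, t, 4)

  y <- repeated_notch(x, c(1.43, 2.87), fs)
  pk <- find_spec_peaks(periodogram_spec(y, fs))
  expect_false(any(abs(pk$bpm - 86.06) < 2))
  expect_false(any(abs(pk$bpm - 172.1) < 2))
  expect_equal(pk$bpm[1], 60 * 2.72, tolerance = 2)

  # duplicates count once: identical output to a single application
  expect_equal(repeated_notch(x, c(1.43, 1.43), fs),
               repeated_notch(x, 1.43, fs))
  # permuting the cascade changes nothing (LTI commutativity)
  expect_equal(repeated_notch(x, c(2.87, 1.43), fs),
               repeated_notch(x, c(1.43, 2.87), fs), tolerance = 1e-9)
  expect_equal(repeated_notch(x, numeric(0), fs), x)

  # more than three artifact frequencies: one notch per axis top peak
  axes <- lapply(list(c(1.0, 1.7), c(1.3, 2.1), c(2.5, 0.9)), function(fr) {
    tone(fr[1], t, 1) + tone(fr[2], t, 0.8)
  })
  pks <- acc_peaks_of(axes)
  freqs5 <- c(1.0, 1.7, 1.3, 2.1, 2.5)
  y5 <- repeated_notch(x, freqs5, fs, acc_peaksets = pks)
  # reference: the detected top peak of each axis (bin-quantized frequency)
  top3 <- vapply(pks, function(p) p$freq[which.max(p$amplitude)], numeric(1))
  expect_equal(round(sort(top3), 1), c(1.0, 1.3, 2.5))
  y_ref <- repeated_notch(x, top3, fs)
  expect_equal(y5, y_ref, tolerance = 1e-9)
})

test_that("after notching, the dominant peak returns to the cardiac tone", {
  fs <- 125; t <- (0:999) / fs
  set.seed(8)
  for (i in 1:10) {
    f_hr <- runif(1, 1.0, 2.8)
    f_ma <- runif(1, 0.6, 2.9)
    if (abs(f_hr - f_ma) < 0.2) next
    x <- tone(f_hr, t) + tone(f_ma, t, 3) + rnorm(1000, 0, 0.05)
    y <- repeated_notch(x, f_ma, fs)
    pk <- find_spec_peaks(periodogram_spec(y, fs))
    expect_lt(abs(pk$freq[1] - f_hr), 2 * fs / 4096)
  }
})
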
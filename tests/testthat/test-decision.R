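specs_of <- function(channels, fs = fs_default) {
  lapply(channels, periodogram_spec, fs = fs)
}

test_that("motion detection requires every axis above the PSD threshold", {
  fs <- 125; t <- (0:999) / fs
  quiet <- lapply(1:3, function(i) rep(0, 1000))
  expect_false(detect_motion(specs_of(quiet)))

  # amplitudes chosen so in-band PSD maxima are about (0.5, 0.4, 0.05)
  amp_for <- function(p) sqrt(p * 2 * fs / 1000)
  chans <- list(tone(2, t, amp_for(0.5)), tone(2, t, amp_for(0.4)),
                tone(2, t, amp_for(0.05)))
  expect_false(detect_motion(specs_of(chans)))  # one axis below 0.1
  chans[[3]] <- tone(2, t, amp_for(0.5))
  expect_true(detect_motion(specs_of(chans)))
})

test_that("motion windows of a running segment all trip the detector", {
  cfg <- synth_config(duration = 60, seed = 2,
                      bpm_trajectory = data.frame(time = c(0, 60),
                                                  bpm = c(120, 120)),
                      ma_tones = list(list(freq = 2, amp_ppg = 1, amp_acc = 1,
                                           start = 20, end = 60)))
  rec <- gen_record(cfg)$record
  wins <- slide_windows(rec)
  flags <- vapply(wins, function(w) {
    detect_motion(specs_of(list(w$acc_x, w$acc_y, w$acc_z)))
  }, logical(1))
  # windows fully inside the rest interval are quiet; fully inside motion, loud
  expect_false(any(flags[1:6]))   # windows covering 0-18 s
  expect_true(all(flags[12:27]))  # windows starting at 22 s onwards
})

test_that("acceleration reliability counts per-axis peaks", {
  mk <- function(n) data.frame(freq = seq_len(n), bpm = 60 * seq_len(n),
                               amplitude = rev(seq_len(n)), bin = seq_len(n))
  expect_true(acc_reliable(list(mk(2), mk(3), mk(1))))
  expect_false(acc_reliable(list(mk(2), mk(6), mk(1))))
  # broadband noise: many comparable maxima exceed the cap
  set.seed(9)
  noisy <- lapply(1:3, function(i) rnorm(1000, 0, 3))
  pks <- acc_peaks_of(noisy)
  expect_false(acc_reliable(pks))
})

test_that("acceleration-matched PPG peaks are removed (inclusive tolerance)", {
  # artifact peaks at 86.06 and 172.1 BPM absorb the nearby PPG peaks
  # (inclusive 8-BPM match); only the cardiac peak at 163.2 survives
  ppg <- data.frame(freq = c(86.1, 163.2, 172.1) / 60,
                    bpm = c(86.1, 163.2, 172.1),
                    amplitude = c(3, 1, 5), bin = 1:3)
  acc1 <- data.frame(freq = 86.06 / 60, bpm = 86.06, amplitude = 1, bin = 1L)
  acc2 <- data.frame(freq = 172.1 / 60, bpm = 172.1, amplitude = 1, bin = 2L)
  empty <- acc1[0, ]
  out <- remove_acc_peaks(ppg, list(acc1, acc2, empty), tol = 8)
  expect_equal(out$bpm, 163.2)

  expect_equal(remove_acc_peaks(ppg, list(empty, empty, empty), tol = 8), ppg)

  # a peak exactly tol away is removed
  ppg_b <- data.frame(freq = 1, bpm = 100, amplitude = 1, bin = 1L)
  acc_b <- data.frame(freq = 1, bpm = 108, amplitude = 1, bin = 2L)
  expect_equal(nrow(remove_acc_peaks(ppg_b, list(acc_b, empty, empty), 8)), 0L)

  # idempotent, and anti-monotone in the tolerance
  once <- remove_acc_peaks(ppg, list(acc1, acc2, empty), 8)
  expect_equal(remove_acc_peaks(once, list(acc1, acc2, empty), 8), once)
  for (tol in c(2, 5, 10, 20)) {
    expect_lte(nrow(remove_acc_peaks(ppg, list(acc1, acc2, empty), tol + 2)),
               nrow(remove_acc_peaks(ppg, list(acc1, acc2, empty), tol)))
  }
})

test_that("the two ternary decisions route to the documented cases", {
  mk <- function(bpms) data.frame(freq = bpms / 60, bpm = bpms,
                                  amplitude = rev(seq_along(bpms)),
                                  bin = seq_along(bpms))
  none <- mk(numeric(0))
  expect_equal(route_window(none, 150)$route, "CASE3")
  expect_equal(route_window(none, 150)$level, 1L)

  one <- route_window(mk(150.2), 152)
  expect_equal(one$route, "CASE4")

  several <- route_window(mk(c(120, 150, 155)), 152)
  expect_equal(several$route, "CASE5")  # 150 and 155 both within 8
  expect_equal(sort(several$peaks$bpm), c(150, 155))

  far <- route_window(mk(c(110, 120, 130)), 170)
  expect_equal(far$route, "CASE3")
  expect_equal(far$level, 2L)

  single_near <- route_window(mk(c(120, 150)), 152)
  expect_equal(single_near$route, "CASE4")
  expect_equal(single_near$peaks$bpm, 150)
})
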
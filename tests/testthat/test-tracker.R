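test_that("configuration validation rejects non-positive thresholds", {
  expect_s3_class(tracker_config(), "tracker_config")
  expect_error(tracker_config(th_pass = 0), "th_pass")
  expect_error(tracker_config(th_acc_peaks = -1), "th_acc_peaks")
  expect_error(tracker_config(notch_r = 1), "notch_r")
  expect_error(tracker_config(band = c(3, 0.5)), "band")
})

test_that("initialization waits for a single-peaked raw periodogram", {
  fs <- 125; t <- (0:999) / fs
  multi <- tone(1.2, t) + tone(2.2, t)
  single <- tone(1.2, t)
  mkw <- function(x, i) {
    w <- make_window(x, rep(0, 1000), rep(0, 1000), rep(0, 1000))
    w$index <- i
    w
  }
  init <- initialize_tracker(list(mkw(single, 0L)))
  expect_equal(init$index, 0L)
  expect_equal(init$bpm, 72, tolerance = 1)

  init2 <- initialize_tracker(list(mkw(multi, 0L), mkw(multi, 1L),
                                   mkw(multi, 2L), mkw(single, 3L)))
  expect_equal(init2$index, 3L)

  expect_error(initialize_tracker(list(mkw(multi, 0L))), "initialization failed")

  # a clean rest-start record initializes within its first windows
  g <- gen_record(synth_config(duration = 30, seed = 4,
                               bpm_trajectory = data.frame(time = c(0, 30),
                                                           bpm = c(72, 72))))
  expect_lte(initialize_tracker(slide_windows(g$record))$index, 2L)
})

test_that("peak gating is strict and falls back on the previous estimate", {
  g <- nfeemd:::gate_strict
  expect_equal(g(151, 148, 8), list(bpm = 151, accepted = TRUE))
  expect_equal(g(170, 148, 8), list(bpm = 148, accepted = FALSE))
  expect_equal(g(156, 148, 8), list(bpm = 148, accepted = FALSE))  # |d| = 8 rejected
  expect_equal(g(NA_real_, 148, 8), list(bpm = 148, accepted = FALSE))
})

test_that("output smoothing averages the recent raw estimates", {
  expect_equal(smooth_output(150), 150)
  expect_equal(smooth_output(c(148, 150, 152), window = 3), 150)
  expect_error(smooth_output(numeric(0)), "empty")
  # a 140 -> 160 step is reached monotonically within `window` steps
  hist <- c(rep(140, 5), rep(160, 8))
  sm <- vapply(6:13, function(k) smooth_output(hist[1:k], 5), numeric(1))
  expect_true(all(diff(sm) >= 0))
  expect_equal(sm[5:8], rep(160, 4))
})

test_that("the masked-peak case follows notch first, then decomposition", {
  fs <- 125; t <- (0:999) / fs
  cfg <- tracker_config()
  set.seed(5)
  # cardiac tone at 163.2 BPM buried under strong artifact tones at the
  # frequencies visible in the acceleration channels
  ppg <- tone(2.72, t) + tone(1.43, t, 4, 1) + tone(2.87, t, 4, 2) +
    rnorm(1000, 0, 0.05)
  accs <- lapply(1:3, function(i) tone(1.43, t, 1, i) + tone(2.87, t, 0.8, i) +
                   rnorm(1000, 0, 0.02))
  w <- make_window(ppg, accs[[1]], accs[[2]], accs[[3]])
  res <- nfeemd:::case3_estimate(w, 160, 1L, acc_peaks_of(accs), cfg,
                                 eemd_seed = 1)
  expect_equal(res$method, "NF")
  expect_true(res$accepted)
  expect_lt(abs(res$bpm - 163.2), 4)

  # artifact fully overlapping the cardiac tone: notching removes both and
  # the decomposition path recovers the rate
  ppg2 <- 3 * tone(2.5633, t) + 6 * tone(1.28, t, 1, 1) + rnorm(1000, 0, 0.05)
  accs2 <- lapply(1:3, function(i) 1.2 * tone(1.28, t, 1, i) +
                    tone(2.5633, t, 1, 2 * i) + rnorm(1000, 0, 0.02))
  w2 <- make_window(ppg2, accs2[[1]], accs2[[2]], accs2[[3]])
  res2 <- nfeemd:::case3_estimate(w2, 155.6, 1L, acc_peaks_of(accs2), cfg,
                                  eemd_seed = 1)
  expect_equal(res2$method, "EEMD")
  expect_lt(abs(res2$bpm - 153.8), 5)

  # both paths implausible: hold the previous value
  quiet <- make_window(rnorm(1000, 0, 0.01), accs[[1]], accs[[2]], accs[[3]])
  res3 <- nfeemd:::case3_estimate(quiet, 60, 1L, acc_peaks_of(accs), cfg,
                                  eemd_seed = 1)
  if (!res3$accepted) expect_equal(res3$bpm, 60)
})

test_that("the pipeline is deterministic and audit-jump bounded", {
  g <- gen_record(gen_scenario("notch_regime", seed = 2))
  cfg <- tracker_config()
  r1 <- run_pipeline(g$record, cfg, seed = 9)
  r2 <- run_pipeline(g$record, cfg, seed = 9)
  expect_identical(r1, r2)
  raw <- r1$bpm_raw[is.finite(r1$bpm_raw)]
  expect_true(all(abs(diff(raw)) <= max(cfg$th_pass, cfg$calib2_accept)))
  expect_true(all(raw > 30 & raw < 240))
  # every processed window carries exactly one route label
  expect_false(any(is.na(r1$route)))
})
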
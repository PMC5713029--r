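test_that("window count, indexing and overlap follow the 8 s / 2 s protocol", {
  rec <- new_record(ppg = seq_len(4750), acc_x = rnorm(4750),
                    acc_y = rnorm(4750), acc_z = rnorm(4750), fs = 125)
  w <- slide_windows(rec)
  expect_length(w, 16L)  # floor((4750 - 1000)/250) + 1
  expect_equal(w[[1]]$start_sample, 0L)
  expect_equal(w[[2]]$start_sample, 250L)  # 2-s stride = 6-s overlap
  expect_equal(w[[2]]$ppg[1], rec$ppg[251])
  expect_length(w[[1]]$ppg, 1000L)

  rec8 <- new_record(seq_len(1000), rnorm(1000), rnorm(1000), rnorm(1000),
                     fs = 125)
  expect_length(slide_windows(rec8), 1L)
  rec_short <- new_record(seq_len(999), rnorm(999), rnorm(999), rnorm(999),
                          fs = 125)
  expect_error(slide_windows(rec_short), "shorter than one analysis window")
})

test_that("window count formula matches brute-force enumeration", {
  set.seed(11)
  for (i in 1:20) {
    L <- sample(1000:6000, 1)
    fs <- sample(c(25, 50, 125), 1)
    ws <- sample(4:10, 1)
    ss <- sample(1:4, 1)
    W <- round(ws * fs); S <- round(ss * fs)
    if (L < W) next
    rec <- new_record(seq_len(L), numeric(L), numeric(L), numeric(L), fs = fs)
    w <- slide_windows(rec, ws, ss)
    # enumerate every stride-aligned start whose window fits entirely
    brute <- length(Filter(function(s) s + W <= L, seq(0, L - 1, by = S)))
    expect_length(w, brute)
    # concatenated strides of consecutive windows rebuild the record interior
    if (length(w) >= 3L && S <= W) {
      strided <- unlist(lapply(w, function(x) x$ppg[seq_len(S)]))
      expect_equal(strided, rec$ppg[seq_len(S * length(w))])
    }
  }
})

test_that("records reject NaN and mismatched channels", {
  expect_error(new_record(c(1, NaN, 3), 1:3, 1:3, 1:3, fs = 125), "NaN")
  expect_error(new_record(1:4, 1:3, 1:3, 1:3, fs = 125), "equal length")
  expect_error(new_record(1:3, 1:3, 1:3, 1:3, fs = 0), "fs must be positive")
})

test_that("CSV round-trip preserves samples and truth; errors are informative", {
  n <- 1200
  rec <- new_record(rnorm(n), rnorm(n), rnorm(n), rnorm(n), fs = 125,
                    truth_bpm = c(72.5, 74, 75.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_csv_record(rec, f)
  back <- load_csv_record(f, fs = 125)
  expect_equal(back$ppg, rec$ppg)
  expect_equal(back$acc_z, rec$acc_z)
  expect_equal(back$truth_bpm, rec$truth_bpm)

  df <- data.frame(ppg = rnorm(10), acc_x = rnorm(10), acc_y = rnorm(10))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  expect_error(load_csv_record(f2, 125), "acc_z")

  df3 <- data.frame(ppg = rnorm(10), acc_x = rnorm(10), acc_y = rnorm(10),
                    acc_z = rnorm(10), junk = letters[1:10])
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df3, f3, row.names = FALSE)
  expect_silent(load_csv_record(f3, 125))
})

test_that("MAT-file reader agrees with an independently written file", {
  f <- tempfile(fileext = ".mat")
  ft <- tempfile(fileext = ".mat")
  code <- sprintf(paste0(
    "import numpy, scipy.io; ",
    "m = numpy.arange(60, dtype=float).reshape(6, 10); ",
    "scipy.io.savemat(%s, {'sig': m}, do_compression=True); ",
    "scipy.io.savemat(%s, {'BPM0': numpy.array([70.0, 71.5, 73.0])})"),
    shQuote(f), shQuote(ft))
  status <- system2("python", c("-c", shQuote(code)))
  expect_identical(status, 0L)

  rec <- load_spcup_record(f, ppg_channel = 1, truth_path = ft)
  expect_length(rec$ppg, 10L)
  expect_equal(rec$fs, 125)
  # numpy reshape(6, 10) is row-major: row 2 (PPG1) holds 10..19
  expect_equal(rec$ppg, as.numeric(10:19))
  expect_equal(rec$acc_z, as.numeric(50:59))
  expect_equal(rec$truth_bpm, c(70, 71.5, 73))
  rec2 <- load_spcup_record(f, ppg_channel = 2)
  expect_equal(rec2$ppg, as.numeric(20:29))

  # MAT round trip through CSV keeps samples bit-identical
  fc <- withr::local_tempfile(fileext = ".csv")
  write_csv_record(rec, fc)
  expect_equal(load_csv_record(fc, 125)$ppg, rec$ppg)

  # undersized matrix is a format error naming the file
  f5 <- tempfile(fileext = ".mat")
  code5 <- sprintf(
    "import numpy, scipy.io; scipy.io.savemat(%s, {'sig': numpy.zeros((5, 10))})",
    shQuote(f5))
  system2("python", c("-c", shQuote(code5)))
  expect_error(load_spcup_record(f5), "no signal matrix")
  expect_error(load_spcup_record(tempfile()), "cannot open")
  expect_error(load_spcup_record(f, ppg_channel = 3), "ppg_channel")
})
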
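# Shared fixture builders: everything is generated in code at test time.

fs_default <- 125

tone <- function(f, t, amp = 1, phase = 0) amp * sin(2 * pi * f * t + phase)

# One analysis window built directly from channel vectors.
make_window <- function(ppg, acc_x, acc_y, acc_z, fs = fs_default) {
  structure(list(index = 0L, ppg = ppg, acc_x = acc_x, acc_y = acc_y,
                 acc_z = acc_z, fs = fs, start_sample = 0L),
            class = "nfeemd_window")
}

# A smooth random signal: white noise through a circular moving average.
random_smooth <- function(n = 1000, m = 20) {
  as.numeric(stats::filter(rnorm(n), rep(1 / m, m), circular = TRUE))
}

acc_peaks_of <- function(channels, fs = fs_default, nfft = 4096) {
  lapply(channels, function(ch) {
    find_spec_peaks(periodogram_spec(ch, fs, nfft = nfft))
  })
}
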
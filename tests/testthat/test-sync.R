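# trigger pulse train on a device's own clock: events at true times
# `times`, device started `offset` s after the true origin, clock running
# (1 + drift_ppm e-6) slow/fast
pulse_trace <- function(n, fs, times_true, offset = 0, drift_ppm = 0,
                        amp = 100, width_s = 0.04) {
  y <- numeric(n)
  for (t in times_true) {
    tau <- (t - offset) / (1 + drift_ppm * 1e-6)
    i <- 1L + round(tau * fs)
    if (i >= 1 && i <= n) y[i:min(n, i + round(width_s * fs) - 1L)] <- amp
  }
  y
}

test_that("trigger detection finds isolated pulses and rejects flat traces", {
  fs <- 250
  tr <- pulse_trace(40 * fs, fs, c(1.0, 31.0))
  ev <- detect_triggers(tr, fs)
  expect_length(ev, 2L)
  expect_equal(ev, c(1.0, 31.0), tolerance = 1 / fs)
  expect_identical(detect_triggers(numeric(1000), fs), numeric(0))
  expect_error(detect_triggers(tr, fs, threshold = 1.2), "threshold")
})

test_that("pulses embedded in noise are recovered exactly at SNR 10", {
  fs <- 250
  times <- c(5, 35, 65, 95)
  set.seed(42)
  tr <- pulse_trace(120 * fs, fs, times, amp = 10) + rnorm(120 * fs, sd = 1)
  ev <- detect_triggers(tr, fs)
  expect_length(ev, length(times))
  expect_equal(ev, times, tolerance = 2 / fs)
})

test_that("a constant inter-device offset is recovered within one sample of the slower stream", {
  fs_a <- 2000; fs_b <- 250
  times <- seq(5, 295, by = 30)
  offset <- 2.345
  recA <- eeg_recording(matrix(rnorm(300 * fs_a), ncol = 1), fs_a,
                        trigger = pulse_trace(300 * fs_a, fs_a, times))
  recB <- eeg_recording(matrix(rnorm(300 * fs_b), ncol = 1), fs_b,
                        trigger = pulse_trace(300 * fs_b, fs_b, times,
                                              offset = offset))
  al <- align_pair(recA, recB)
  # B started `offset` late, so its events appear early on its own clock
  expect_equal(al$offset_s, -offset, tolerance = 1 / fs_b)
  expect_equal(al$recB_aligned$start_offset_s, offset, tolerance = 1 / fs_b)
  expect_lt(max(abs(al$residual_s)), 1 / fs_b + 1e-9)
})

test_that("aligning identical recordings gives zero offset and residuals; alignment is idempotent", {
  fs <- 250
  rec <- eeg_recording(matrix(rnorm(100 * fs), ncol = 1), fs,
                       trigger = pulse_trace(100 * fs, fs, c(5, 35, 65)))
  al <- align_pair(rec, rec)
  expect_identical(al$offset_s, 0)
  expect_identical(max(abs(al$residual_s)), 0)
  al2 <- align_pair(rec, al$recB_aligned)
  expect_lt(abs(al2$offset_s), 1 / fs + 1e-9)
  # missing triggers on either side make synchronization impossible
  dead <- rec; dead$trigger <- numeric(100 * fs)
  expect_error(align_pair(rec, dead), "missing triggers")
})

test_that("20 ppm drift over an hour leaves residuals under the 0.1-s lag budget", {
  fs <- 250
  times <- seq(5, 3595, by = 60)
  recA <- eeg_recording(matrix(0 + rnorm(3600 * fs, sd = 1e-3), ncol = 1), fs,
                        trigger = pulse_trace(3600 * fs, fs, times))
  recB <- eeg_recording(matrix(rnorm(3600 * fs, sd = 1e-3), ncol = 1), fs,
                        trigger = pulse_trace(3600 * fs, fs, times,
                                              drift_ppm = 20))
  al <- align_pair(recA, recB)
  # closed form: accumulated drift 20e-6 * 3600 = 0.072 s end to end
  spread <- diff(range(al$matched_triggers$time_B_s -
                         al$matched_triggers$time_A_s))
  expect_equal(spread, 0.072, tolerance = 0.006)
  # median-offset removal leaves every pair within the lag tolerance
  expect_lt(max(abs(al$residual_s)), 0.1)
})

test_that("resampling preserves duration and in-band amplitude while killing out-of-band tones", {
  fs <- 2000
  rec10 <- make_rec(tone(10, fs, 80, amp = 10), fs)
  out10 <- resample_recording(rec10, 250)
  expect_equal(n_samples(out10), 20000L)          # 80 s x 250 Hz
  mid <- 5000:15000
  expect_equal(max(abs(out10$data[mid, 1])), 10, tolerance = 0.01)
  out140 <- resample_recording(make_rec(tone(140, fs, 80, amp = 10), fs), 250)
  atten_db <- 20 * log10(max(abs(out140$data[mid, 1])) / 10)
  expect_lt(atten_db, -20)
  expect_error(resample_recording(out10, 2000), "upsampling")
})

test_that("broadband FIR is zero-mean on DC, unity in band, and >=20 dB down at 50 Hz", {
  fs <- 250
  dc <- bandpass_fir(make_rec(rep(50, 40 * fs), fs), 0.3, 35)
  expect_lt(abs(mean(dc$data[, 1])), 1e-6)
  mid <- 3000:7000
  y10 <- bandpass_fir(make_rec(tone(10, fs, 40, amp = 10), fs), 0.3, 35)
  gain_db <- 20 * log10(max(abs(y10$data[mid, 1])) / 10)
  expect_lt(abs(gain_db), 1)
  y50 <- bandpass_fir(make_rec(tone(50, fs, 40, amp = 10), fs), 0.3, 35)
  expect_lt(20 * log10(max(abs(y50$data[mid, 1])) / 10), -20)
  expect_error(bandpass_fir(make_rec(rnorm(1000), fs), 0.3, 130), "Nyquist|band")
})

test_that("filtering is linear and commutes with resampling for in-band signals", {
  fs <- 250
  set.seed(7)
  x <- rnorm(30 * fs); y <- rnorm(30 * fs)
  lhs <- bandpass_fir(2 * x + 3 * y, 0.3, 35, fs = fs)
  rhs <- 2 * bandpass_fir(x, 0.3, 35, fs = fs) +
    3 * bandpass_fir(y, 0.3, 35, fs = fs)
  expect_equal(lhs, rhs, tolerance = 1e-8)

  fs_hi <- 1000
  sig <- make_rec(tone(10, fs_hi, 60, amp = 5) + tone(20, fs_hi, 60, amp = 2),
                  fs_hi)
  a <- bandpass_fir(resample_recording(sig, 250), 0.3, 35)
  b <- resample_recording(bandpass_fir(sig, 0.3, 35), 250)
  mid <- 4000:11000
  expect_equal(a$data[mid, 1], b$data[mid, 1], tolerance = 0.05)
})
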
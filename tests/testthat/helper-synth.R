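# shared test utilities

# independent periodogram band-power oracle (raw periodogram, no taper)
oracle_band_power <- function(x, fs, low, high) {
  s <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                         taper = 0, detrend = TRUE)
  sum(s$spec[s$freq >= low & s$freq < high])
}

make_rec <- function(x, fs, ...) {
  eeg_recording(matrix(x, ncol = 1, dimnames = list(NULL, "ch")), fs, ...)
}

tone <- function(freq, fs, dur_s, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(dur_s * fs) - 1)) / fs + phase)
}

# minimal epoch grid for functions that only need flags
fake_grid <- function(flags, epoch_len_s = 10) {
  structure(list(artifact_flag = flags, epoch_len_s = epoch_len_s),
            class = "epoch_grid")
}

# light alpha-test config used across tests: two scalp channels keeps the
# synthesis cheap while exercising the full dual-device path
quick_alpha_cfg <- function(seed, n_trials = 10, ...) {
  sim_config("alpha_test", n_trials = n_trials,
             scalp_channels = c("T7", "T8"), artifact_rate = 0,
             seed = seed, ...)
}
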
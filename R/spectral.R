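# Time-frequency decomposition, the alpha-band SNR statistic, and relative
# spectral power in the canonical EEG bands.

#' Canonical EEG frequency bands
#'
#' The five bands partition 0.3-35 Hz exactly: delta 0.3-4, theta 4-8,
#' alpha 8-12, beta1 12-18, beta2 18-35 Hz. Band membership is half-open
#' `[low, high)` except the last band, which closes at 35 Hz, so relative
#' powers sum to one.
#'
#' @return data.frame with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta1", "beta2"),
             low_hz = c(0.3, 4, 8, 12, 18),
             high_hz = c(4, 8, 12, 18, 35))
}

#' Construct a spectral estimate
#'
#' Frequencies must be strictly increasing; power is nonnegative, either a
#' vector (time-averaged spectrum) or a time x frequency matrix.
#'
#' @param freqs Hz grid.
#' @param power nonnegative vector or matrix (rows = time points).
#' @param window_len_s,method metadata.
#' @param valid optional logical vector over time rows marking samples away
#'   from edge effects.
#' @return object of class `spectral_estimate`.
#' @export
spectral_estimate <- function(freqs, power, window_len_s = NA_real_,
                              method = "fft_window", valid = NULL) {
  stopifnot(all(diff(freqs) > 0), all(power >= 0))
  if (is.matrix(power)) stopifnot(ncol(power) == length(freqs))
  else stopifnot(length(power) == length(freqs))
  structure(list(freqs = freqs, power = power, window_len_s = window_len_s,
                 method = method, valid = valid),
            class = "spectral_estimate")
}

#' Gabor (Morlet-family) wavelet spectrogram
#'
#' Time-resolved power by convolution with complex Gabor wavelets: a
#' Gaussian-windowed complex exponential per frequency with a fixed number
#' of cycles (constant-Q). Kernels are unit-energy (L2-normalized), so a
#' flat-spectrum (white) signal yields a flat time-averaged power profile
#' across frequencies, and a pure tone's power peaks at the grid point
#' nearest its frequency. Time points within one wavelet half-length of
#' either edge are marked invalid.
#'
#' @param x numeric signal in microvolts.
#' @param fs sampling rate in Hz.
#' @param freqs frequency grid in Hz, strictly inside (0, fs/2).
#' @param cycles wavelet cycles (>= 3); default 7.
#' @return a [spectral_estimate()] with a time x frequency power matrix and
#'   a `valid` flag per time sample.
#' @export
gabor_spectrogram <- function(x, fs, freqs, cycles = 7) {
  stopifnot(is.numeric(x), fs > 0, cycles >= 3)
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("frequencies must lie strictly inside (0, fs/2)")
  n <- length(x)
  pow <- matrix(0, nrow = n, ncol = length(freqs))
  max_half <- 0L
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma_t <- cycles / (2 * pi * f)
    half <- ceiling(4 * sigma_t * fs)
    max_half <- max(max_half, half)
    tt <- (-half:half) / fs
    g <- exp(-tt^2 / (2 * sigma_t^2))
    kern <- g * exp(2i * pi * f * tt)
    kern <- kern / sqrt(sum(Mod(kern)^2))  # unit energy
    # complex FFT convolution, zero-phase (kernel symmetric envelope)
    re <- apply_fir_complex(kern, x, half)
    pow[, j] <- Mod(re)^2
  }
  valid <- rep(TRUE, n)
  if (max_half > 0 && n > 2 * max_half) {
    valid[seq_len(max_half)] <- FALSE
    valid[(n - max_half + 1L):n] <- FALSE
  } else if (n <= 2 * max_half) valid[] <- FALSE
  spectral_estimate(freqs, pow, method = "gabor_wavelet", valid = valid)
}

# complex-kernel convolution with zero padding, delay-compensated
apply_fir_complex <- function(kern, x, half) {
  n <- length(x)
  L <- length(kern)
  m <- stats::nextn(n + L - 1L, 2)
  X <- stats::fft(c(x, rep(0, m - n)))
  K <- stats::fft(c(kern, rep(0, m - L)))
  y <- stats::fft(X * K, inverse = TRUE) / m
  y[half + seq_len(n)]
}

#' Alpha-band signal-to-noise ratio
#'
#' Mean spectral power over 8-12 Hz divided by mean power over 5-35 Hz
#' excluding 7-13 Hz (the surrounding-noise band). A ratio above 1.5 is
#' flagged as a "clear alpha peak". For a time-resolved estimate the
#' spectrum is first averaged over valid time points (optionally restricted
#' with `time_keep`, e.g. clean eyes-closed samples).
#'
#' @param est a [spectral_estimate()] covering 5-35 Hz.
#' @param time_keep optional logical vector over time rows to include.
#' @param clear_peak_thresh ratio defining a clear peak; default 1.5.
#' @return list with `snr` (unitless ratio), `clear_peak` (logical),
#'   `snr_db` (amplitude dB, see [snr_to_db()]).
#' @export
snr_alpha <- function(est, time_keep = NULL, clear_peak_thresh = 1.5) {
  stopifnot(inherits(est, "spectral_estimate"))
  f <- est$freqs
  if (min(f) > 5 || max(f) < 35)
    stop("spectral estimate must cover 5-35 Hz")
  spec <- if (is.matrix(est$power)) {
    keep <- if (is.null(est$valid)) rep(TRUE, nrow(est$power)) else est$valid
    if (!is.null(time_keep)) keep <- keep & time_keep
    if (!any(keep)) stop("no valid time points to average over")
    colMeans(est$power[keep, , drop = FALSE])
  } else est$power
  sig <- f >= 8 & f <= 12
  noi <- f >= 5 & f <= 35 & !(f >= 7 & f <= 13)
  den <- mean(spec[noi])
  if (den == 0) stop("undefined SNR: zero power in the noise band")
  snr <- mean(spec[sig]) / den
  list(snr = snr, clear_peak = snr > clear_peak_thresh,
       snr_db = snr_to_db(snr))
}

#' Convert an SNR ratio to amplitude decibels
#'
#' Amplitude convention, `20 * log10(ratio)`: the clear-peak criterion of
#' 1.5 corresponds to a 3.52 dB amplitude difference over the surrounding
#' noise.
#'
#' @param ratio positive unitless ratio.
#' @return decibels.
#' @export
snr_to_db <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  20 * log10(ratio)
}

#' Time-averaged FFT spectrum over fixed windows
#'
#' Hann-tapered periodograms of consecutive non-overlapping windows,
#' averaged into a single spectrum — the FFT-window counterpart of the
#' wavelet estimate, as used for relative band power.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param window_len_s window length in seconds; default 10.
#' @param mask optional logical per window, `TRUE` to exclude.
#' @return a [spectral_estimate()] (`method = "fft_window"`).
#' @export
fft_spectrum <- function(x, fs, window_len_s = 10, mask = NULL) {
  spw <- round(window_len_s * fs)
  n_win <- floor(length(x) / spw)
  if (n_win < 1L) stop("signal shorter than one window")
  if (is.null(mask)) mask <- rep(FALSE, n_win)
  keep <- which(!mask)
  if (length(keep) == 0L) stop("no clean windows")
  acc <- NULL
  for (w in keep) {
    ps <- window_psd(x[((w - 1L) * spw + 1L):(w * spw)], fs)
    acc <- if (is.null(acc)) ps[, "psd"] else acc + ps[, "psd"]
  }
  freqs <- window_psd(x[seq_len(spw)], fs)[, "freq"]
  spectral_estimate(freqs, acc / length(keep), window_len_s = window_len_s,
                    method = "fft_window")
}

# Hann-tapered periodogram of one window: two-column matrix (freq, psd)
window_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  X <- stats::fft((x - mean(x)) * w)
  k <- seq_len(floor(n / 2))               # positive frequencies
  cbind(freq = k * fs / n, psd = Mod(X[k + 1L])^2)
}

#' Relative spectral power in the canonical bands
#'
#' Cuts the signal into fixed non-overlapping windows, computes a
#' Hann-tapered FFT periodogram per clean window, and forms the relative
#' power of each canonical band as the summed PSD in the band divided by
#' the summed PSD over 0.3-35 Hz. Relative powers are averaged across
#' windows and sum to one by construction.
#'
#' @param x numeric signal in microvolts.
#' @param fs sampling rate in Hz.
#' @param mask optional logical vector, one element per window, `TRUE` for
#'   artifact windows to exclude (e.g. `epoch_grid$artifact_flag`).
#' @param window_len_s window length in seconds; default 10.
#' @param label condition/stage label attached to the output.
#' @return object of class `band_power_table`: data.frame with columns
#'   `band`, `low_hz`, `high_hz`, `rsp`, plus attributes `n_windows` and
#'   `label`. If no clean window exists, a zero-row table with
#'   `status = "no clean data"`.
#' @export
relative_band_power <- function(x, fs, mask = NULL, window_len_s = 10,
                                label = NA_character_) {
  spw <- round(window_len_s * fs)
  n_win <- floor(length(x) / spw)
  if (n_win < 1L) stop("signal shorter than one window")
  if (is.null(mask)) mask <- rep(FALSE, n_win)
  stopifnot(length(mask) == n_win)
  bands <- eeg_bands()
  keep <- which(!mask)
  if (length(keep) == 0L) {
    out <- bands[0, ]
    out$rsp <- numeric(0)
    attr(out, "status") <- "no clean data"
    attr(out, "n_windows") <- 0L
    attr(out, "label") <- label
    class(out) <- c("band_power_table", class(out))
    return(out)
  }
  rsp_mat <- vapply(keep, function(w) {
    seg <- x[((w - 1L) * spw + 1L):(w * spw)]
    ps <- window_psd(seg, fs)
    total <- ps[, "freq"] >= 0.3 & ps[, "freq"] <= 35
    denom <- sum(ps[total, "psd"])
    if (denom == 0) return(rep(NA_real_, nrow(bands)))
    vapply(seq_len(nrow(bands)), function(b) {
      inb <- if (b == nrow(bands))
        ps[, "freq"] >= bands$low_hz[b] & ps[, "freq"] <= bands$high_hz[b]
      else
        ps[, "freq"] >= bands$low_hz[b] & ps[, "freq"] < bands$high_hz[b]
      sum(ps[inb & total, "psd"]) / denom
    }, numeric(1))
  }, numeric(nrow(bands)))
  out <- cbind(bands, rsp = rowMeans(rsp_mat, na.rm = TRUE))
  attr(out, "status") <- "ok"
  attr(out, "n_windows") <- length(keep)
  attr(out, "rsp_windows") <- rsp_mat     # bands x windows, for inference
  attr(out, "label") <- label
  class(out) <- c("band_power_table", class(out))
  out
}
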
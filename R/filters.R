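# Windowed-sinc FIR design and zero-phase application.
#
# The band-pass is built as the difference of two Hamming-windowed sinc
# low-pass kernels so the two transition bands can be set independently:
# the default broadband filter (0.3-35 Hz) needs a very sharp low edge
# (0.3 Hz wide, to kill slow drifts without eating delta) but only a 5 Hz
# edge at the top. Kernels are linear-phase (symmetric, odd length); the
# group delay is removed exactly after FFT convolution, so filtering is
# zero-phase in a single pass.

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Hamming-windowed sinc low-pass; cutoff = -6 dB point in Hz.
# Transition width (Hz) sets the kernel order: ~3.3 / normalized width.
fir_lowpass_kernel <- function(cutoff_hz, fs, trans_hz) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2, trans_hz > 0)
  n <- ceiling(3.3 / (trans_hz / fs))
  if (n %% 2L == 1L) n <- n + 1L          # even order -> odd length, type I
  m <- 0:n
  x <- m - n / 2
  h <- (2 * cutoff_hz / fs) * sinc(2 * cutoff_hz / fs * x)
  w <- 0.54 - 0.46 * cos(2 * pi * m / n)
  b <- h * w
  b / sum(b)                               # unity gain at DC
}

# Band-pass kernel: LP(high) - LP(low), both centered on the same tap.
fir_bandpass_kernel <- function(low_hz, high_hz, fs,
                                trans_low_hz = min(low_hz, 2),
                                trans_high_hz = min(5, high_hz / 3)) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < fs / 2)
  bl <- fir_lowpass_kernel(low_hz, fs, trans_low_hz)
  bh <- fir_lowpass_kernel(high_hz, fs, trans_high_hz)
  L <- max(length(bl), length(bh))
  pad <- function(b) {
    k <- (L - length(b)) / 2
    c(rep(0, k), b, rep(0, k))
  }
  pad(bh) - pad(bl)
}

# Zero-phase FIR filtering by FFT convolution with reflection padding.
# b must be symmetric (linear phase); the (L-1)/2 delay is removed exactly.
apply_fir <- function(b, x) {
  L <- length(b)
  half <- (L - 1L) / 2L
  n <- length(x)
  p <- min(half, n - 1L)
  # anti-symmetric reflection continues the local trend, limiting edge bias
  left  <- if (p > 0) 2 * x[1] - x[(p + 1L):2L] else numeric(0)
  right <- if (p > 0) 2 * x[n] - x[n - seq_len(p)] else numeric(0)
  xp <- c(left, x, right)
  # full convolution xp * b via power-of-2 padded FFT (arbitrary-length
  # FFTs in R can hit slow prime factorizations)
  np <- length(xp)
  m <- stats::nextn(np + L - 1L, 2)
  X <- stats::fft(c(xp, rep(0, m - np)))
  Bf <- stats::fft(c(b, rep(0, m - L)))
  y <- Re(stats::fft(X * Bf, inverse = TRUE)) / m
  y[(half + p) + seq_len(n)]
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a linear-phase windowed-sinc band-pass to every channel of a
#' recording (group delay compensated, so the output is zero-phase). The
#' default transition widths follow the broadband EEG convention: a sharp
#' low edge to suppress slow electrode drifts and a relaxed high edge.
#'
#' @param rec an [eeg_recording()] (or a bare numeric vector, in which case
#'   `fs` must be given and a vector is returned).
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @param fs sampling rate, only for vector input.
#' @param trans_low,trans_high transition widths in Hz at each edge.
#' @return filtered recording (or vector). The trigger channel is left
#'   untouched.
#' @export
bandpass_fir <- function(rec, low, high, fs = NULL,
                         trans_low = min(low, 2),
                         trans_high = min(5, high / 3)) {
  if (is.numeric(rec) && is.null(dim(rec))) {
    stopifnot(!is.null(fs))
    if (!(low > 0 && low < high && high < fs / 2))
      stop("band edges must satisfy 0 < low < high < fs/2")
    b <- fir_bandpass_kernel(low, high, fs, trans_low, trans_high)
    return(apply_fir(b, rec))
  }
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  b <- fir_bandpass_kernel(low, high, rec$fs, trans_low, trans_high)
  out <- rec
  out$data <- apply(rec$data, 2L, function(ch) apply_fir(b, ch))
  dimnames(out$data) <- dimnames(rec$data)
  out
}

#' Resample a recording to a lower rate
#'
#' Anti-alias filters with a windowed-sinc low-pass (cutoff 0.45 x target
#' rate, transition 0.1 x target rate) and then samples the filtered signal
#' at the new sample times by linear interpolation. Upsampling is refused:
#' the harmonization step only ever brings the faster scalp stream down to
#' the in-ear rate.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs new sampling rate in Hz, `<= rec$fs`.
#' @return resampled `eeg_recording`; duration preserved to within one
#'   output sample; the trigger channel is resampled the same way.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"), target_fs > 0)
  if (target_fs > rec$fs) stop("upsampling is not supported (target_fs > fs)")
  if (target_fs == rec$fs) return(rec)
  n_in <- nrow(rec$data)
  n_out <- floor(n_in * target_fs / rec$fs)
  t_in <- (seq_len(n_in) - 1L) / rec$fs
  t_out <- (seq_len(n_out) - 1L) / target_fs
  b <- fir_lowpass_kernel(0.45 * target_fs, rec$fs, 0.1 * target_fs)
  res1 <- function(ch) {
    stats::approx(t_in, apply_fir(b, ch), xout = t_out)$y
  }
  dat <- vapply(seq_len(ncol(rec$data)),
                function(j) res1(rec$data[, j]), numeric(n_out))
  colnames(dat) <- colnames(rec$data)
  eeg_recording(dat, target_fs,
                trigger = if (!is.null(rec$trigger)) res1(rec$trigger),
                start_offset_s = rec$start_offset_s)
}
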
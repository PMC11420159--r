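# Synthetic paired in-ear / scalp EEG generator.
#
# Shared-source model: within each condition the two devices see the same
# oscillatory source. The scalp derivation carries amp_ratio x the source
# plus independent noise; the in-ear channel carries the source plus its
# own noise; noise variances are calibrated against the empirically
# measured band SDs of the source and background so the in-ear vs
# scalp-derivation correlation hits a target rho in expectation. The
# in-ear stream is sampled through a warped clock (constant offset +
# linear drift), and both streams carry the same rectangular trigger
# pulses, so synchronization and correlation recovery are genuine
# parameter-recovery exercises.

default_scalp_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT11", "FC3", "FCz", "FC4", "FT12",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
}

default_stage_template <- function() {
  # per-stage band SDs in microvolts (in-ear scale)
  list(
    Wake = c(delta = 1.0, theta = 1.5, alpha = 5.0, spindle = 0.5),
    N1   = c(delta = 1.5, theta = 4.0, alpha = 1.5, spindle = 0.5),
    N2   = c(delta = 2.0, theta = 2.5, alpha = 1.0, spindle = 3.5),
    N3   = c(delta = 9.0, theta = 4.0, alpha = 0.5, spindle = 1.0),
    REM  = c(delta = 1.5, theta = 3.0, alpha = 1.0, spindle = 0.5))
}

stage_band_edges <- function() {
  list(delta = c(0.5, 2), theta = c(4, 7), alpha = c(8, 12),
       spindle = c(12, 16))
}

#' Simulation configuration
#'
#' Collects every knob of the paired-recording generator with defaults
#' matching the study conditions the analysis assumes: 10 alternating 30-s
#' eyes-closed/eyes-open trials beginning with eyes closed (5-min alpha
#' session), ~1-h naps with 30-s staged epochs, in-ear at 250 Hz, scalp at
#' 2000 Hz with 10-10 labels, a 2x scalp/in-ear alpha amplitude ratio, and
#' movement artifacts 5-10x the brain-signal amplitude.
#'
#' @param protocol `"alpha_test"` or `"nap"`.
#' @param n_trials alpha-test trial count (even; default 10).
#' @param trial_len_s trial length in seconds (default 30).
#' @param session_len_s optional total alpha-session length; must equal
#'   `n_trials * trial_len_s` when given.
#' @param nap_len_s nap length in seconds (default 3600).
#' @param fs_inear,fs_scalp device sampling rates in Hz (250 / 2000).
#' @param scalp_channels 10-10 labels (<= 64).
#' @param amp_ratio scalp/in-ear alpha amplitude ratio (default 2).
#' @param alpha_freq alpha carrier frequency in Hz (default 10).
#' @param alpha_sd SD of the stochastic 8-12 Hz shared source, microvolts,
#'   in-ear scale (default 6).
#' @param alpha_carrier_amp amplitude of the sinusoidal alpha carrier with
#'   random phase per trial, microvolts (default 3).
#' @param bg_sd SD of the 1/f background per channel, microvolts
#'   (default 5).
#' @param rho target alpha-band in-ear vs T7-T8 correlation (default 0.5).
#' @param rho_stage named per-stage target broadband correlations for naps.
#' @param artifact_rate transient artifact events per minute (default 0.5).
#' @param artifact_amp_factor artifact peak over background RMS
#'   (default 10, the top of the observed 5-10x range).
#' @param contact_loss_prob probability an epoch suffers contact loss
#'   (default 0).
#' @param clock_offset_s in-ear clock start minus scalp clock start,
#'   seconds (default 0.5).
#' @param clock_drift_ppm linear in-ear clock drift, parts per million
#'   (default 20).
#' @param trigger_times_s shared pulse times on the true timeline; default
#'   one pulse per trial (alpha) or per minute (nap), starting at 5 s.
#' @param stage_template named list stage -> band SDs (microvolts) over
#'   `delta`, `theta`, `alpha`, `spindle` components.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   output.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(protocol = c("alpha_test", "nap"),
                       n_trials = 10, trial_len_s = 30,
                       session_len_s = NULL, nap_len_s = 3600,
                       fs_inear = 250, fs_scalp = 2000,
                       scalp_channels = default_scalp_channels(),
                       amp_ratio = 2, alpha_freq = 10,
                       alpha_sd = 6, alpha_carrier_amp = 3, bg_sd = 5,
                       rho = 0.5,
                       rho_stage = c(Wake = 0.45, N1 = 0.50, N2 = 0.50,
                                     N3 = 0.62, REM = 0.48),
                       artifact_rate = 0.5, artifact_amp_factor = 10,
                       contact_loss_prob = 0,
                       clock_offset_s = 0.5, clock_drift_ppm = 20,
                       trigger_times_s = NULL,
                       stage_template = default_stage_template(),
                       seed = 1) {
  protocol <- match.arg(protocol)
  if (fs_inear <= 0 || fs_scalp <= 0) stop("sampling rates must be positive")
  if (amp_ratio <= 0) stop("amp_ratio must be positive")
  if (any(c(n_trials, trial_len_s, nap_len_s, alpha_sd, bg_sd,
            artifact_rate, contact_loss_prob, alpha_carrier_amp) < 0))
    stop("rates, durations and amplitudes must be nonnegative")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (length(scalp_channels) > 64) stop("at most 64 scalp channels")
  if (protocol == "alpha_test") {
    if (n_trials %% 2L != 0L)
      stop("configuration error: alpha test needs an even trial count ",
           "(equal eyes-closed and eyes-open trials, beginning eyes-closed)")
    if (!is.null(session_len_s) &&
        abs(session_len_s - n_trials * trial_len_s) > 1e-9)
      stop("configuration error: session_len_s != n_trials * trial_len_s")
  }
  if (is.null(trigger_times_s)) {
    trigger_times_s <- if (protocol == "alpha_test")
      5 + trial_len_s * (seq_len(n_trials) - 1L)
    else seq(5, nap_len_s - 10, by = 60)
  }
  structure(list(protocol = protocol, n_trials = n_trials,
                 trial_len_s = trial_len_s, nap_len_s = nap_len_s,
                 fs_inear = fs_inear, fs_scalp = fs_scalp,
                 scalp_channels = scalp_channels, amp_ratio = amp_ratio,
                 alpha_freq = alpha_freq, alpha_sd = alpha_sd,
                 alpha_carrier_amp = alpha_carrier_amp, bg_sd = bg_sd,
                 rho = rho, rho_stage = rho_stage,
                 artifact_rate = artifact_rate,
                 artifact_amp_factor = artifact_amp_factor,
                 contact_loss_prob = contact_loss_prob,
                 clock_offset_s = clock_offset_s,
                 clock_drift_ppm = clock_drift_ppm,
                 trigger_times_s = trigger_times_s,
                 stage_template = stage_template, seed = seed),
            class = "sim_config")
}

# --- spectral-shaping primitives (FFT masks on white noise) -------------

# Gaussian noise band-limited to [low, high] Hz, unit SD
band_noise <- function(n, fs, low, high) {
  if (n < 8L) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  X[f < low | f > high] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# 1/f-amplitude background, high-passed at 0.3 Hz, unit SD
pink_noise <- function(n, fs) {
  if (n < 8L) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f < 0.3, 0, 1 / sqrt(f))
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

# SD of x restricted to [low, high] Hz (FFT mask measurement)
band_sd <- function(x, fs, low, high) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  X[f < low | f > high] <- 0
  stats::sd(Re(stats::fft(X, inverse = TRUE)) / n)
}

# raised-cosine boxcar over [a, b) seconds with ramp_s edges
smooth_gate <- function(t, a, b, ramp_s = 0.25) {
  g <- numeric(length(t))
  inside <- t >= a & t < b
  g[inside] <- 1
  if (ramp_s > 0) {
    up <- t >= a & t < a + ramp_s
    g[up] <- 0.5 - 0.5 * cos(pi * (t[up] - a) / ramp_s)
    dn <- t >= b - ramp_s & t < b
    g[dn] <- 0.5 + 0.5 * cos(pi * (t[dn] - (b - ramp_s)) / ramp_s)
  }
  g
}

# shared slow amplitude modulation: one bounded factor per 10-s span,
# piecewise constant and coherent across both devices. Spans alternate
# randomly between alpha-poor and alpha-rich states (alpha blocking /
# bursting), jittered within state — oscillatory power waxes and wanes in
# bouts, as resting alpha does, over a ~5-10x amplitude range without
# extreme outliers.
shared_envelope <- function(n, fs, span_s = 10, p_rich = 0.5) {
  n_span <- ceiling(n / (span_s * fs))
  rich <- stats::runif(n_span) < p_rich
  u <- ifelse(rich, stats::runif(n_span, 2.0, 2.6),
              stats::runif(n_span, 0.25, 0.55))
  rep(u, each = round(span_s * fs))[seq_len(n)]
}

# gentler continuous modulation for sleep-stage processes: stage
# oscillations wax and wane moderately, without the on/off bout structure
# of waking alpha
stage_envelope <- function(n, fs, span_s = 10, lo = 0.7, hi = 1.3) {
  n_span <- ceiling(n / (span_s * fs))
  u <- stats::runif(n_span, lo, hi)
  rep(u, each = round(span_s * fs))[seq_len(n)]
}

# rectangular trigger pulse train on the master grid
trigger_trace <- function(n, fs, times_s, width_s = 0.04, amp = 1) {
  y <- numeric(n)
  w <- max(1L, round(width_s * fs))
  for (t0 in times_s) {
    i <- 1L + round(t0 * fs)
    if (i >= 1L && i <= n) y[i:min(n, i + w - 1L)] <- amp
  }
  y
}

# electrode number of a 10-10 label ("FT11" -> 11; NA for midline)
parse_label_num <- function(lab) {
  if (!grepl("^[A-Za-z]+[0-9]+$", lab)) return(NA_integer_)
  as.integer(sub("^[A-Za-z]+", "", lab))
}

# spatial gain of the shared source on a homologous electrode pair
pair_gain <- function(label) {
  base <- sub("[0-9]+$", "", label)
  num <- parse_label_num(label)
  if (is.na(num)) return(0)
  switch(base,
         "T" = if (num %in% c(7, 8)) 1.0 else 0.2,
         "FT" = if (num %in% c(11, 12)) 0.85 else 0.4,
         "TP" = 0.7,
         "P" = if (num %in% c(7, 8)) 0.5 else 0.35,
         "F" = if (num %in% c(7, 8)) 0.5 else 0.25,
         "C" = 0.3,
         0.2)
}

# sample a master-grid series through the in-ear's warped clock:
# in-ear sample k (device time k/fs) sees true time offset + tau*(1+drift)
warp_to_inear <- function(master, fs_master, n_out, fs_inear,
                          offset_s, drift_ppm) {
  tau <- (seq_len(n_out) - 1L) / fs_inear
  t_true <- offset_s + tau * (1 + drift_ppm * 1e-6)
  t_master <- (seq_along(master) - 1L) / fs_master
  stats::approx(t_master, master, xout = t_true, rule = 2)$y
}

# noise-SD calibration for a target correlation between
#   inear = z + s1*e1 + bg   and   deriv = a*(z + s2u*e2) + bg_deriv
# using measured band SDs of source (s) and backgrounds (b1, bd)
calib_noise_sd <- function(s, rho, a, b1, bd) {
  v <- s^2 * (1 - rho) / rho
  s1 <- sqrt(max(0, v - b1^2))
  s2u <- sqrt(max(0, v - bd^2 / a^2))       # in units of the source scale
  c(inear = s1, deriv = s2u)
}

#' Generate a synthetic eyes-closed / eyes-open alpha session
#'
#' Builds paired in-ear and scalp recordings for the alternating 30-s
#' eyes-closed/eyes-open protocol (always beginning eyes closed). During
#' eyes-closed trials a shared alpha source (band-limited 8-12 Hz noise
#' plus a sinusoidal carrier with random phase per trial, both under a
#' slow shared amplitude envelope) appears on the in-ear channel and — at
#' `amp_ratio` strength — on the contralateral scalp electrodes, strongest
#' at T7/T8. Eyes-open trials contain 1/f background only. Both devices
#' carry the same rectangular trigger pulses; the in-ear stream is sampled
#' through its offset-and-drifting clock.
#'
#' @param config a [sim_config()] with `protocol = "alpha_test"`.
#' @return list with `inear` and `scalp` [eeg_recording()]s, `schedule`
#'   (data.frame: trial, condition, start/end on the true timeline),
#'   and `truth` (clock parameters, target rho, component SDs).
#' @export
generate_alpha_test <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$protocol != "alpha_test")
    stop("configuration error: protocol must be 'alpha_test'")
  set.seed(config$seed)
  fs <- config$fs_scalp
  dur <- config$n_trials * config$trial_len_s
  margin <- config$clock_offset_s + 1
  n <- round((dur + margin) * fs)
  t <- (seq_len(n) - 1L) / fs

  sched <- data.frame(
    trial = seq_len(config$n_trials),
    condition = rep(c("EC", "EO"), length.out = config$n_trials),
    start_s = config$trial_len_s * (seq_len(config$n_trials) - 1L))
  sched$end_s <- sched$start_s + config$trial_len_s

  # eyes-closed gate with soft edges
  gate <- numeric(n)
  for (i in which(sched$condition == "EC"))
    gate <- gate + smooth_gate(t, sched$start_s[i], sched$end_s[i])

  # shared alpha source: band noise + per-trial random-phase carrier
  z <- config$alpha_sd * band_noise(n, fs, 8, 12)
  carrier <- numeric(n)
  for (i in which(sched$condition == "EC")) {
    ph <- stats::runif(1, 0, 2 * pi)
    seg <- t >= sched$start_s[i] & t < sched$end_s[i]
    carrier[seg] <- config$alpha_carrier_amp *
      sin(2 * pi * config$alpha_freq * t[seg] + ph)
  }
  env <- shared_envelope(n, fs)
  z <- (z + carrier) * env * gate

  # backgrounds and independent alpha-band device noise (same envelope)
  bg_in <- config$bg_sd * pink_noise(n, fs)
  b1 <- band_sd(bg_in, fs, 8, 12)
  s_meas <- stats::sd(z[gate > 0.99])
  # derivation background = difference of two independent channel
  # backgrounds -> sqrt(2) x the per-channel alpha-band SD
  bd <- sqrt(2) * config$bg_sd * band_sd(pink_noise(n, fs), fs, 8, 12)
  sds <- calib_noise_sd(s_meas, config$rho, config$amp_ratio, b1, bd)
  # normalize after envelope gating so the realized gated SD equals the
  # calibrated value (the envelope would otherwise inflate it by E[u^2])
  gated_noise <- function(target_sd) {
    raw <- band_noise(n, fs, 8, 12) * env * gate
    s <- stats::sd(raw[gate > 0.99])
    if (s == 0 || target_sd == 0) return(raw * 0)
    raw * target_sd / s
  }
  e1 <- gated_noise(sds["inear"])
  e2 <- gated_noise(sds["deriv"])

  # scalp channels: per-channel background plus a lateralized alpha bundle.
  # Each homologous pair mixes the shared temporal source (weight g) with
  # its own independent alpha source (weight sqrt(1 - g^2)), keeping total
  # alpha power constant across pairs while the correlation with the
  # in-ear channel scales with g — temporal pairs correlate most.
  shared_bundle <- z + e2
  s2tot <- stats::sd(shared_bundle[gate > 0.99])
  own_sources <- new.env(parent = emptyenv())
  pair_key <- function(lab) {
    num <- parse_label_num(lab)
    if (is.na(num)) return(NA_character_)
    base <- sub("[0-9]+$", "", lab)
    paste0(base, if (num %% 2L == 1L) num else num - 1L)
  }
  scalp <- vapply(config$scalp_channels, function(lab) {
    bg <- config$bg_sd * pink_noise(n, fs)
    key <- pair_key(lab)
    if (is.na(key)) return(bg)               # midline: background only
    g <- pair_gain(lab)
    if (is.null(own_sources[[key]]))
      own_sources[[key]] <- gated_noise(s2tot)
    side <- if (parse_label_num(lab) %% 2L == 1L) 1 else -1
    bundle <- g * shared_bundle + sqrt(max(0, 1 - g^2)) * own_sources[[key]]
    bg + side * (config$amp_ratio / 2) * bundle
  }, numeric(n))
  colnames(scalp) <- config$scalp_channels

  trig_amp <- 10 * config$bg_sd
  trig <- trigger_trace(n, fs, config$trigger_times_s, amp = trig_amp)

  rec_scalp <- eeg_recording(scalp[seq_len(round(dur * fs)), , drop = FALSE],
                             fs, trigger = trig[seq_len(round(dur * fs))])

  inear_master <- z + e1 + bg_in
  n_in <- round(dur * config$fs_inear)
  inear <- warp_to_inear(inear_master, fs, n_in, config$fs_inear,
                         config$clock_offset_s, config$clock_drift_ppm)
  trig_in <- warp_to_inear(trig, fs, n_in, config$fs_inear,
                           config$clock_offset_s, config$clock_drift_ppm)
  rec_inear <- eeg_recording(matrix(inear, ncol = 1,
                                    dimnames = list(NULL, "InEar")),
                             config$fs_inear, trigger = trig_in)

  list(inear = rec_inear, scalp = rec_scalp, schedule = sched,
       truth = list(clock_offset_s = config$clock_offset_s,
                    clock_drift_ppm = config$clock_drift_ppm,
                    rho = config$rho, amp_ratio = config$amp_ratio,
                    source_sd = s_meas, noise_sd = sds,
                    trigger_times_s = config$trigger_times_s),
       config = config)
}

# deterministic-ish nap architecture: stage runs truncated to nap length
nap_stage_sequence <- function(n_epochs) {
  cycle <- c(rep("Wake", 4), rep("N1", 4), rep("N2", 8), rep("N3", 8),
             rep("N2", 4), rep("REM", 4), rep("N1", 2))
  stages <- rep(cycle, length.out = max(n_epochs, length(cycle)))
  stages[seq_len(n_epochs)]
}

#' Generate a synthetic nap with hypnogram
#'
#' Stage-structured paired recordings: each 30-s epoch carries the
#' oscillatory mixture of its stage (Wake: ~10 Hz alpha; N1/N3: 4-7 Hz
#' theta; N2: 12-16 Hz spindle-band activity; N3: 0.5-2 Hz slow waves),
#' shared between devices at `amp_ratio` scalp gain with per-stage
#' correlation targets, on top of independent 1/f backgrounds. Returns the
#' hypnogram that downstream staging-dependent analyses consume.
#'
#' @param config a [sim_config()] with `protocol = "nap"`.
#' @return list with `inear`, `scalp`, `hypnogram`, `truth`.
#' @export
generate_nap <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$protocol != "nap")
    stop("configuration error: protocol must be 'nap'")
  set.seed(config$seed)
  fs <- config$fs_scalp
  n_epochs <- floor(config$nap_len_s / 30)
  dur <- n_epochs * 30
  margin <- config$clock_offset_s + 1
  n <- round((dur + margin) * fs)

  stages <- nap_stage_sequence(n_epochs)
  missing_tpl <- setdiff(unique(stages), names(config$stage_template))
  if (length(missing_tpl) > 0)
    stop("configuration error: stage_template lacks stage(s): ",
         paste(missing_tpl, collapse = ", "))
  hyp <- hypnogram(stages)

  edges <- stage_band_edges()
  stage_process <- function(len, tpl) {
    out <- numeric(len)
    for (bn in names(edges))
      if (!is.na(tpl[bn]) && tpl[bn] > 0)
        out <- out + tpl[bn] * band_noise(len, fs, edges[[bn]][1],
                                          edges[[bn]][2])
    out
  }

  bg_in <- config$bg_sd * pink_noise(n, fs)
  bg_T7 <- config$bg_sd * pink_noise(n, fs)
  bg_T8 <- config$bg_sd * pink_noise(n, fs)
  b1 <- band_sd(bg_in, fs, 0.3, 35)
  bd <- band_sd(bg_T7 - bg_T8, fs, 0.3, 35)

  z <- numeric(n); e1 <- numeric(n); e2 <- numeric(n)
  # contiguous runs of the same stage are synthesized as one segment
  run_id <- cumsum(c(TRUE, stages[-1] != stages[-n_epochs]))
  for (rid in unique(run_id)) {
    eps <- which(run_id == rid)
    st <- stages[eps[1]]
    i0 <- round((eps[1] - 1) * 30 * fs) + 1L
    i1 <- min(n, round(eps[length(eps)] * 30 * fs))
    len <- i1 - i0 + 1L
    tpl <- config$stage_template[[st]]
    env <- stage_envelope(len, fs)
    zz <- stage_process(len, tpl) * env
    s <- stats::sd(zz)                     # realized (post-envelope) SD
    rho_st <- unname(config$rho_stage[st])
    if (is.na(rho_st)) rho_st <- config$rho
    sds <- calib_noise_sd(s, rho_st, config$amp_ratio, b1, bd)
    mk_noise <- function(target_sd) {
      raw <- stage_process(len, tpl) * env
      sr <- stats::sd(raw)
      if (sr == 0 || target_sd == 0) return(raw * 0)
      raw * target_sd / sr
    }
    z[i0:i1] <- zz
    e1[i0:i1] <- mk_noise(sds["inear"])
    e2[i0:i1] <- mk_noise(sds["deriv"])
  }

  src_scalp <- config$amp_ratio * (z + e2)
  labs <- config$scalp_channels
  scalp <- vapply(labs, function(lab) {
    bg <- switch(lab, "T7" = bg_T7, "T8" = bg_T8,
                 config$bg_sd * pink_noise(n, fs))
    g <- pair_gain(lab)
    num <- parse_label_num(lab)
    side <- if (is.na(num)) 0 else if (num %% 2L == 1L) 1 else -1
    bg + side * (g / 2) * src_scalp
  }, numeric(n))
  colnames(scalp) <- labs

  trig_amp <- 10 * config$bg_sd
  trig <- trigger_trace(n, fs, config$trigger_times_s, amp = trig_amp)
  rec_scalp <- eeg_recording(scalp[seq_len(round(dur * fs)), , drop = FALSE],
                             fs, trigger = trig[seq_len(round(dur * fs))])

  inear_master <- z + e1 + bg_in
  n_in <- round(dur * config$fs_inear)
  inear <- warp_to_inear(inear_master, fs, n_in, config$fs_inear,
                         config$clock_offset_s, config$clock_drift_ppm)
  trig_in <- warp_to_inear(trig, fs, n_in, config$fs_inear,
                           config$clock_offset_s, config$clock_drift_ppm)
  rec_inear <- eeg_recording(matrix(inear, ncol = 1,
                                    dimnames = list(NULL, "InEar")),
                             config$fs_inear, trigger = trig_in)

  list(inear = rec_inear, scalp = rec_scalp, hypnogram = hyp,
       truth = list(clock_offset_s = config$clock_offset_s,
                    clock_drift_ppm = config$clock_drift_ppm,
                    rho_stage = config$rho_stage,
                    amp_ratio = config$amp_ratio,
                    trigger_times_s = config$trigger_times_s),
       config = config)
}

#' Inject transient artifacts and contact-loss epochs
#'
#' Adds movement-like transients (Gaussian-windowed deflections, peak
#' amplitude `artifact_amp_factor` x the channel's per-epoch median RMS)
#' at a Poisson rate, and whole-epoch contact-loss events (large slow
#' swings) with probability `contact_loss_prob` per 10-s epoch. With rate
#' and probability both zero the recording is returned unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param config a [sim_config()] (uses `artifact_rate`,
#'   `artifact_amp_factor`, `contact_loss_prob`, `seed`).
#' @return list with `rec` (contaminated copy) and `truth` (data.frame of
#'   injected intervals: type, start_s, end_s, channel).
#' @export
inject_artifacts <- function(rec, config) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(config, "sim_config"))
  if (config$artifact_rate == 0 && config$contact_loss_prob == 0)
    return(list(rec = rec,
                truth = data.frame(type = character(0),
                                   start_s = numeric(0), end_s = numeric(0),
                                   channel = character(0))))
  set.seed(config$seed + 7919L)
  fs <- rec$fs
  dur <- rec_duration(rec)
  out <- rec
  truth <- list()
  for (ch in colnames(rec$data)) {
    x <- out$data[, ch]
    spe <- round(10 * fs)
    n_ep <- floor(length(x) / spe)
    rms_scale <- sqrt(mean(x^2))        # whole-channel background RMS
    peak <- config$artifact_amp_factor * rms_scale
    n_ev <- stats::rpois(1, config$artifact_rate * dur / 60)
    if (n_ev > 0) {
      starts <- sort(stats::runif(n_ev, 0, dur - 0.6))
      for (s0 in starts) {
        w <- stats::runif(1, 0.2, 0.5)
        i <- (1L + round(s0 * fs)):min(length(x), round((s0 + w) * fs))
        tt <- seq_along(i) / fs
        shape <- exp(-((tt - w / 2)^2) / (2 * (w / 6)^2))
        x[i] <- x[i] + sample(c(-1, 1), 1) * peak * shape
        truth[[length(truth) + 1L]] <-
          data.frame(type = "transient", start_s = s0, end_s = s0 + w,
                     channel = ch)
      }
    }
    if (config$contact_loss_prob > 0) {
      lost <- which(stats::runif(n_ep) < config$contact_loss_prob)
      for (ep in lost) {
        i <- ((ep - 1L) * spe + 1L):(ep * spe)
        tt <- seq_along(i) / fs
        amp <- max(1.5 * peak, 150)
        x[i] <- x[i] + amp * sin(2 * pi * 0.7 * tt +
                                   stats::runif(1, 0, 2 * pi))
        truth[[length(truth) + 1L]] <-
          data.frame(type = "contact_loss", start_s = (ep - 1) * 10,
                     end_s = ep * 10, channel = ch)
      }
    }
    out$data[, ch] <- x
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth)
  else data.frame(type = character(0), start_s = numeric(0),
                  end_s = numeric(0), channel = character(0))
  list(rec = out, truth = truth)
}

#' Write a simulation to plain-text files
#'
#' One CSV per device plus a JSON sidecar holding the ground truth
#' (schedule or hypnogram, clock parameters, targets); the hypnogram also
#' as two-column CSV.
#'
#' @param sim result of [generate_alpha_test()] or [generate_nap()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording_csv(sim$inear, file.path(dir, "inear.csv"))
  write_recording_csv(sim$scalp, file.path(dir, "scalp.csv"))
  side <- sim$truth
  if (!is.null(sim$schedule)) side$schedule <- sim$schedule
  jsonlite::write_json(side, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(sim$hypnogram))
    write_hypnogram_csv(sim$hypnogram, file.path(dir, "hypnogram.csv"))
  invisible(dir)
}
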
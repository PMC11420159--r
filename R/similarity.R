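# In-ear vs scalp similarity: contralateral bipolar derivations,
# lag-tolerant cross-correlation, per-stage correlations, agreement
# categories, and the alpha amplitude-ratio slope.

#' Build contralateral bipolar derivations from 10-10 labels
#'
#' Pairs each left-hemisphere electrode (odd-numbered label) with its
#' right-hemisphere homolog (the next even number: T7-T8, FT11-FT12,
#' P1-P2, ...). Midline electrodes (z suffix) and electrodes whose homolog
#' is absent are skipped and reported.
#'
#' @param channel_labels character vector of 10-10 electrode names.
#' @return data.frame with columns `name`, `left`, `right`; skipped labels
#'   in `attr(, "skipped")`.
#' @export
contralateral_montage <- function(channel_labels) {
  m <- regmatches(channel_labels,
                  regexec("^([A-Za-z]+?)([0-9]+|z)$", channel_labels))
  parsed <- lapply(m, function(g) if (length(g) == 3L) g[2:3] else NULL)
  skipped <- character(0)
  pairs <- list()
  for (i in seq_along(channel_labels)) {
    lab <- channel_labels[i]
    p <- parsed[[i]]
    if (is.null(p) || identical(p[2], "z")) { skipped <- c(skipped, lab); next }
    num <- as.integer(p[2])
    if (num %% 2L == 0L) next               # right electrodes picked up via left
    homolog <- paste0(p[1], num + 1L)
    if (homolog %in% channel_labels) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(name = paste0(lab, "-", homolog), left = lab,
                   right = homolog)
    } else skipped <- c(skipped, lab)
  }
  right_unpaired <- vapply(seq_along(channel_labels), function(i) {
    p <- parsed[[i]]
    !is.null(p) && !identical(p[2], "z") && as.integer(p[2]) %% 2L == 0L &&
      !paste0(p[1], as.integer(p[2]) - 1L) %in% channel_labels
  }, logical(1))
  skipped <- c(skipped, channel_labels[right_unpaired])
  if (length(pairs) == 0L)
    stop("no pairable contralateral electrodes in the montage")
  out <- do.call(rbind, pairs)
  attr(out, "skipped") <- skipped
  out
}

#' Derivation signals for a montage
#'
#' @param rec an [eeg_recording()] whose channels include every electrode
#'   named in `montage`.
#' @param montage data.frame from [contralateral_montage()].
#' @return numeric matrix (samples x derivations, left minus right),
#'   columns named after the derivations.
#' @export
apply_montage <- function(rec, montage) {
  out <- vapply(seq_len(nrow(montage)), function(i) {
    get_channel(rec, montage$left[i]) - get_channel(rec, montage$right[i])
  }, numeric(nrow(rec$data)))
  colnames(out) <- montage$name
  out
}

#' Lag-tolerant normalized cross-correlation
#'
#' Pearson correlation of `a` against `b` at every integer-sample lag in
#' `[-max_lag_s, +max_lag_s]`; returns the signed correlation at the lag
#' maximizing `|r|`. A positive `best_lag_s` means `b` lags (is delayed
#' relative to) `a`. The tolerance window absorbs residual inter-clock
#' drift that a single fixed lag would miss.
#'
#' @param a,b equal-length numeric series (>= 2 samples).
#' @param fs sampling rate in Hz.
#' @param max_lag_s maximum absolute lag in seconds (default 0.1).
#' @return list with `r`, `best_lag_s`, and the full `lags_s` / `r_all`
#'   profiles.
#' @export
xcorr_max <- function(a, b, fs, max_lag_s = 0.1) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 2L, max_lag_s >= 0)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero-variance input")
  K <- round(max_lag_s * fs)
  K <- min(K, n - 2L)
  lags <- -K:K
  rs <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(a[seq_len(n - k)], b[seq_len(n - k) + k])
    else stats::cor(a[seq_len(n + k) - k], b[seq_len(n + k)])
  }, numeric(1))
  i <- which.max(abs(rs))
  list(r = rs[i], best_lag_s = lags[i] / fs,
       lags_s = lags / fs, r_all = rs)
}

#' Alpha-band correlation map over scalp derivations
#'
#' Correlates the in-ear channel with every contralateral scalp derivation
#' over concatenated clean eyes-closed windows (all series already aligned,
#' at a common rate, and alpha band-passed). Feed the result to
#' [permutation_corr_test()] / [bh_fdr()] for inference.
#'
#' @param inear numeric in-ear series (alpha band-passed).
#' @param derivations samples x derivations matrix from [apply_montage()]
#'   (alpha band-passed).
#' @param fs common sampling rate in Hz.
#' @param mask logical per 10-s window; `TRUE` windows (artifact or
#'   eyes-open) are excluded before correlating.
#' @param window_len_s window length used by `mask`; default 10.
#' @param max_lag_s lag tolerance; default 0.1.
#' @return data.frame, one row per derivation: `derivation`, `r`,
#'   `best_lag_s`, `n_windows`.
#' @export
alpha_correlation_map <- function(inear, derivations, fs, mask = NULL,
                                  window_len_s = 10, max_lag_s = 0.1) {
  stopifnot(is.matrix(derivations), nrow(derivations) == length(inear))
  spw <- round(window_len_s * fs)
  n_win <- floor(length(inear) / spw)
  if (is.null(mask)) mask <- rep(FALSE, n_win)
  stopifnot(length(mask) == n_win)
  keep_idx <- unlist(lapply(which(!mask), function(w)
    ((w - 1L) * spw + 1L):(w * spw)))
  if (length(keep_idx) == 0L) stop("no clean windows: no clean data")
  a <- inear[keep_idx]
  res <- lapply(seq_len(ncol(derivations)), function(j) {
    xc <- xcorr_max(a, derivations[keep_idx, j], fs, max_lag_s)
    data.frame(derivation = colnames(derivations)[j], r = xc$r,
               best_lag_s = xc$best_lag_s, n_windows = sum(!mask))
  })
  do.call(rbind, res)
}

#' Per-sleep-stage correlation between in-ear and scalp
#'
#' Correlates the two broadband (0.3-35 Hz) series within each clean 10-s
#' window, assigns each window the stage of its containing 30-s hypnogram
#' epoch, and summarizes per stage: plain mean r, Fisher-z-back-transformed
#' mean, dispersion, and window count. Stages absent from the hypnogram
#' are omitted.
#'
#' @param inear,scalp aligned equal-length broadband series.
#' @param hyp a [hypnogram()].
#' @param fs sampling rate in Hz.
#' @param mask logical per 10-s window (artifact exclusion), or `NULL`.
#' @param window_len_s default 10; must divide the 30-s epoch length.
#' @param max_lag_s lag tolerance; default 0.1.
#' @return data.frame per observed stage: `stage`, `mean_r`, `mean_r_z`
#'   (Fisher-z average), `sd_r`, `n_windows`; windows' per-window values in
#'   `attr(, "windows")`. Stages with zero clean windows are listed in
#'   `attr(, "omitted")`.
#' @export
stage_correlations <- function(inear, scalp, hyp, fs, mask = NULL,
                               window_len_s = 10, max_lag_s = 0.1) {
  stopifnot(length(inear) == length(scalp))
  spw <- round(window_len_s * fs)
  n_win <- floor(length(inear) / spw)
  if (is.null(mask)) mask <- rep(FALSE, n_win)
  stopifnot(length(mask) == n_win)
  win_per_epoch <- 30 / window_len_s
  win_stage <- as.character(hyp$stage[floor((seq_len(n_win) - 1L) /
                                              win_per_epoch) + 1L])
  rows <- list(); win_tab <- list()
  omitted <- character(0)
  for (st in intersect(c("Wake", "N1", "N2", "N3", "REM"),
                       unique(win_stage))) {
    wins <- which(win_stage == st & !mask)
    if (length(wins) == 0L) { omitted <- c(omitted, st); next }
    rs <- vapply(wins, function(w) {
      i <- ((w - 1L) * spw + 1L):(w * spw)
      xcorr_max(inear[i], scalp[i], fs, max_lag_s)$r
    }, numeric(1))
    z <- atanh(pmin(pmax(rs, -0.999999), 0.999999))
    rows[[st]] <- data.frame(stage = st, mean_r = mean(rs),
                             mean_r_z = tanh(mean(z)),
                             sd_r = stats::sd(rs), n_windows = length(rs))
    win_tab[[st]] <- data.frame(stage = st, window = wins, r = rs)
  }
  if (length(rows) == 0L) stop("no clean windows in any stage")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "windows") <- do.call(rbind, c(win_tab,
                                           list(make.row.names = FALSE)))
  attr(out, "omitted") <- omitted
  out
}

#' Categorize a correlation's strength of agreement
#'
#' Conventional categories on `|r|`: poor (< 0.2), fair (0.2-0.4), moderate
#' (0.4-0.6), substantial (0.6-0.8), almost perfect (>= 0.8). (The
#' occasionally quoted "poor < 0.02" bound is a typo for 0.2 and is
#' implemented as such.)
#'
#' @param r finite correlation value(s).
#' @return ordered factor of categories.
#' @export
classify_agreement <- function(r) {
  stopifnot(all(is.finite(r)))
  cut(abs(r), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("poor", "fair", "moderate", "substantial",
                 "almost perfect"),
      right = FALSE, ordered_result = TRUE)
}

#' Scalp-to-in-ear amplitude-ratio slope
#'
#' Least-squares slope (intercept included) of the square root of per-epoch
#' scalp alpha power against the square root of per-epoch in-ear alpha
#' power. Square roots put the fit on the amplitude scale, so a device pair
#' whose scalp amplitudes are twice the in-ear amplitudes yields a slope
#' of 2.
#'
#' @param power_scalp,power_inear paired nonnegative per-epoch alpha-band
#'   power values (>= 3 clean pairs).
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
amplitude_ratio <- function(power_scalp, power_inear) {
  stopifnot(length(power_scalp) == length(power_inear),
            all(power_scalp >= 0), all(power_inear >= 0))
  if (length(power_scalp) < 3L) stop("need at least 3 paired epochs")
  x <- sqrt(power_inear); y <- sqrt(power_scalp)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance amplitudes: slope undefined")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = length(x))
}
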
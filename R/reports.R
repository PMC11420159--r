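# End-to-end orchestration of the two study protocols: synchronize,
# harmonize rates, band-limit, reject artifact epochs, and emit the
# summary tables (RMS, bad-data %, SNR, band power, correlation maps,
# stage correlations) with permutation + FDR inference.

# crop two aligned recordings to their overlap, snapped to a grid (30 s by
# default) on the true timeline so 10-s windows line up with trials and
# hypnogram epochs
crop_to_grid <- function(recA, recB, grid_s = 30) {
  stopifnot(recA$fs == recB$fs)
  fs <- recA$fs
  t0 <- ceiling(max(recA$start_offset_s, recB$start_offset_s) / grid_s) * grid_s
  t1 <- floor(min(recA$start_offset_s + rec_duration(recA),
                  recB$start_offset_s + rec_duration(recB)) / grid_s) * grid_s
  if (t1 <= t0) stop("recordings do not overlap by a full grid interval")
  cut <- function(r) {
    from <- 1L + round((t0 - r$start_offset_s) * fs)
    crop_samples(r, from, from + round((t1 - t0) * fs) - 1L)
  }
  out <- list(cut(recA), cut(recB))
  attr(out, "t0") <- t0
  attr(out, "t1") <- t1
  out
}

as_recording <- function(x) {
  if (is.character(x)) read_recording_csv(x) else x
}

prep_pair <- function(inear, scalp, target_fs) {
  al <- align_pair(scalp, inear)          # in-ear re-timed onto scalp clock
  scalp_ds <- resample_recording(scalp, target_fs)
  cr <- crop_to_grid(scalp_ds, al$recB_aligned)
  list(scalp = cr[[1]], inear = cr[[2]], t0 = attr(cr, "t0"),
       alignment = al[c("offset_s", "matched_triggers", "residual_s")])
}

write_report_csv <- function(df, dir, name) {
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  invisible(NULL)
}

#' Run the full eyes-closed/eyes-open (alpha) protocol report
#'
#' Executes synchronization, rate harmonization (250 Hz), broadband
#' 0.3-35 Hz filtering, 10-s epoching with the +/-100 uV / 10% artifact
#' rule, RMS summaries and the right-tail rank-sum device comparison,
#' bad-data percentages, Gabor-wavelet alpha SNR per device over clean
#' eyes-closed data, the alpha-band correlation map over contralateral
#' derivations with block-permutation p-values and BH-FDR decisions, and
#' the scalp/in-ear amplitude-ratio slope.
#'
#' @param config a [sim_config()] (`protocol = "alpha_test"`); the
#'   recordings are generated and, if configured, artifact-contaminated.
#'   Alternatively pass `inear`, `scalp` and `schedule` for existing data.
#' @param inear,scalp [eeg_recording()]s or CSV paths (used when `config`
#'   is `NULL`).
#' @param schedule data.frame with `condition` ("EC"/"EO"), `start_s`,
#'   `end_s` on the true timeline (required without `config`).
#' @param n_perm permutations for the correlation tests (default 1600).
#' @param q FDR level (default 0.05).
#' @param alpha permutation significance level (default 0.01).
#' @param seed seed for the permutation draws (default 1).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return a `study_report` list: `alignment`, `rms`, `rms_comparison_p`,
#'   `bad_data`, `snr`, `correlation_map`, `amplitude_ratio`, `n_windows`,
#'   `params`.
#' @export
run_alpha_report <- function(config = NULL, inear = NULL, scalp = NULL,
                             schedule = NULL, n_perm = 1600, q = 0.05,
                             alpha = 0.01, seed = 1, out_dir = NULL) {
  if (!is.null(config)) {
    sim <- generate_alpha_test(config)
    contaminated <- inject_artifacts(sim$inear, config)
    inear <- contaminated$rec
    scalp <- sim$scalp
    schedule <- sim$schedule
  } else {
    inear <- as_recording(inear); scalp <- as_recording(scalp)
    if (is.null(schedule)) stop("a condition schedule is required")
  }
  fs <- inear$fs
  pp <- prep_pair(inear, scalp, fs)

  montage <- contralateral_montage(colnames(pp$scalp$data))
  deriv_bb <- apply_montage(pp$scalp, montage)
  t7t8 <- if ("T7-T8" %in% montage$name) "T7-T8" else montage$name[1]

  in_bb <- bandpass_fir(get_channel(pp$inear, 1L), 0.3, 35, fs = fs)
  sc_bb <- bandpass_fir(deriv_bb[, t7t8], 0.3, 35, fs = fs)
  rec_in_bb <- eeg_recording(matrix(in_bb, ncol = 1,
                                    dimnames = list(NULL, "InEar")), fs,
                             start_offset_s = pp$inear$start_offset_s)
  rec_sc_bb <- eeg_recording(matrix(sc_bb, ncol = 1,
                                    dimnames = list(NULL, t7t8)), fs,
                             start_offset_s = pp$scalp$start_offset_s)

  grid_in <- epoch_and_flag(rec_in_bb, 1L)
  grid_sc <- epoch_and_flag(rec_sc_bb, 1L)
  mask <- shared_artifact_mask(grid_in, grid_sc)

  shared_grid <- function(g) { g$artifact_flag <- mask; g }
  rms_in <- rms_per_epoch(shared_grid(grid_in))
  rms_sc <- rms_per_epoch(shared_grid(grid_sc))
  rms_p <- if (nrow(rms_in$rms) > 0 && nrow(rms_sc$rms) > 0)
    rank_sum_right(rms_in$rms$rms_uV, rms_sc$rms$rms_uV) else NA_real_

  bad_in <- bad_data_fraction(grid_in)
  bad_sc <- bad_data_fraction(grid_sc)

  # 10-s windows -> containing trial -> EC/EO
  win_start <- pp$t0 + (seq_along(mask) - 1L) * 10
  win_trial <- findInterval(win_start + 1e-9, schedule$start_s)
  win_cond <- ifelse(win_trial >= 1 & win_trial <= nrow(schedule),
                     schedule$condition[pmax(win_trial, 1L)], NA)
  ec_clean <- !mask & !is.na(win_cond) & win_cond == "EC"
  if (!any(ec_clean)) stop("no clean eyes-closed windows: no clean data")

  spw <- round(10 * fs)
  keep_samp <- rep(ec_clean, each = spw)
  length(keep_samp) <- length(in_bb)
  keep_samp[is.na(keep_samp)] <- FALSE

  fgrid <- seq(5, 35, by = 0.5)
  snr_in <- snr_alpha(gabor_spectrogram(in_bb, fs, fgrid),
                      time_keep = keep_samp)
  snr_sc <- snr_alpha(gabor_spectrogram(sc_bb, fs, fgrid),
                      time_keep = keep_samp)

  # alpha-band similarity over concatenated clean EC windows
  in_al <- bandpass_fir(get_channel(pp$inear, 1L), 8, 12, fs = fs)
  deriv_al <- apply(deriv_bb, 2L, bandpass_fir, low = 8, high = 12, fs = fs)
  cmap <- alpha_correlation_map(in_al, deriv_al, fs, mask = !ec_clean)
  idx <- unlist(lapply(which(ec_clean), function(w)
    ((w - 1L) * spw + 1L):(w * spw)))
  cmap$p <- vapply(seq_len(nrow(cmap)), function(i)
    permutation_corr_test(in_al[idx], deriv_al[idx, cmap$derivation[i]],
                          fs, n_perm = n_perm, seed = seed + i,
                          alpha = alpha)$p_two_sided, numeric(1))
  fdr <- bh_fdr(cmap$p, q)
  cmap$p_adj <- fdr$adjusted
  cmap$q_significant <- fdr$reject
  cmap$agreement <- as.character(classify_agreement(cmap$r))

  # per-epoch alpha power (periodogram band sums, so epochs stay
  # independent) on clean EC epochs -> amplitude-ratio slope
  ec_wins <- which(ec_clean)
  alpha_pow <- function(seg) {
    ps <- window_psd(seg, fs)
    inb <- ps[, "freq"] >= 8 & ps[, "freq"] < 12
    sum(ps[inb, "psd"]) / nrow(ps)
  }
  pow <- vapply(ec_wins, function(w) {
    i <- ((w - 1L) * spw + 1L):(w * spw)
    c(inear = alpha_pow(in_bb[i]), scalp = alpha_pow(sc_bb[i]))
  }, numeric(2))
  amp <- if (length(ec_wins) >= 3)
    amplitude_ratio(pow["scalp", ], pow["inear", ]) else NULL

  report <- list(
    protocol = "alpha_test",
    alignment = pp$alignment,
    rms = data.frame(device = c("inear", "scalp"),
                     mean_uV = c(rms_in$summary["mean"], rms_sc$summary["mean"]),
                     sd_uV = c(rms_in$summary["sd"], rms_sc$summary["sd"]),
                     min_uV = c(rms_in$summary["min"], rms_sc$summary["min"]),
                     max_uV = c(rms_in$summary["max"], rms_sc$summary["max"]),
                     n_epochs = c(rms_in$summary["n"], rms_sc$summary["n"])),
    rms_comparison_p = rms_p,
    bad_data = data.frame(device = c("inear", "scalp"),
                          pct = c(bad_in$pct, bad_sc$pct),
                          exceeds_10pct = c(bad_in$exceeds_threshold,
                                            bad_sc$exceeds_threshold)),
    snr = data.frame(device = c("inear", "scalp"),
                     snr_alpha = c(snr_in$snr, snr_sc$snr),
                     snr_db = c(snr_in$snr_db, snr_sc$snr_db),
                     clear_peak = c(snr_in$clear_peak, snr_sc$clear_peak)),
    correlation_map = cmap,
    amplitude_ratio = amp,
    n_windows = c(total = length(mask), clean_ec = sum(ec_clean)),
    params = list(n_perm = n_perm, q = q, alpha = alpha, seed = seed,
                  epoch_len_s = 10, amp_thresh_uV = 100, frac_thresh = 0.1))
  class(report) <- "study_report"
  write_report_csv(report$rms, out_dir, "rms_summary.csv")
  write_report_csv(report$bad_data, out_dir, "bad_data.csv")
  write_report_csv(report$snr, out_dir, "snr.csv")
  write_report_csv(report$correlation_map, out_dir, "correlation_map.csv")
  if (!is.null(out_dir))
    jsonlite::write_json(report$params, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  report
}

#' Run the full nap protocol report
#'
#' Synchronizes and harmonizes the pair, applies the artifact rule, and
#' produces per-stage relative spectral power for both devices with
#' permutation band comparisons under BH-FDR, per-stage in-ear vs scalp
#' correlations, RMS and bad-data summaries. Stages with fewer clean
#' windows than `min_windows` are reported as untested; stages absent from
#' the hypnogram are listed under `not_observed`.
#'
#' @param config a [sim_config()] (`protocol = "nap"`), or `NULL` to use
#'   `inear`, `scalp`, `hyp`.
#' @param inear,scalp [eeg_recording()]s or CSV paths.
#' @param hyp a [hypnogram()] or CSV path (true-timeline 30-s epochs).
#' @param n_perm,q,alpha,seed,out_dir as in [run_alpha_report()].
#' @param min_windows minimum clean windows for a stage to be tested
#'   (default 5).
#' @return a `study_report` list: `alignment`, `rms`, `bad_data`,
#'   `band_power`, `band_comparison`, `stage_correlations`, `not_observed`,
#'   `untested`, `params`.
#' @export
run_nap_report <- function(config = NULL, inear = NULL, scalp = NULL,
                           hyp = NULL, n_perm = 1600, q = 0.05,
                           alpha = 0.01, seed = 1, min_windows = 5,
                           out_dir = NULL) {
  if (!is.null(config)) {
    sim <- generate_nap(config)
    contaminated <- inject_artifacts(sim$inear, config)
    inear <- contaminated$rec
    scalp <- sim$scalp
    hyp <- sim$hypnogram
  } else {
    inear <- as_recording(inear); scalp <- as_recording(scalp)
    if (is.character(hyp)) hyp <- read_hypnogram_csv(hyp)
    if (is.null(hyp)) stop("a hypnogram is required")
  }
  if (abs(nrow(hyp) - floor(rec_duration(inear) / 30)) > 1)
    stop("hypnogram length inconsistent with recording duration")
  fs <- inear$fs
  pp <- prep_pair(inear, scalp, fs)

  montage <- contralateral_montage(colnames(pp$scalp$data))
  t7t8 <- if ("T7-T8" %in% montage$name) "T7-T8" else montage$name[1]
  deriv <- apply_montage(pp$scalp, montage)[, t7t8]

  in_bb <- bandpass_fir(get_channel(pp$inear, 1L), 0.3, 35, fs = fs)
  sc_bb <- bandpass_fir(deriv, 0.3, 35, fs = fs)
  rec_in_bb <- eeg_recording(matrix(in_bb, ncol = 1,
                                    dimnames = list(NULL, "InEar")), fs,
                             start_offset_s = pp$inear$start_offset_s)
  rec_sc_bb <- eeg_recording(matrix(sc_bb, ncol = 1,
                                    dimnames = list(NULL, t7t8)), fs,
                             start_offset_s = pp$scalp$start_offset_s)
  grid_in <- epoch_and_flag(rec_in_bb, 1L)
  grid_sc <- epoch_and_flag(rec_sc_bb, 1L)
  mask <- shared_artifact_mask(grid_in, grid_sc)

  shared_grid <- function(g) { g$artifact_flag <- mask; g }
  rms_in <- rms_per_epoch(shared_grid(grid_in))
  rms_sc <- rms_per_epoch(shared_grid(grid_sc))
  bad_in <- bad_data_fraction(grid_in)
  bad_sc <- bad_data_fraction(grid_sc)

  # crop hypnogram to the analyzed interval
  ep0 <- round(pp$t0 / 30)
  n_ep <- floor(length(in_bb) / (30 * fs))
  hyp_c <- hypnogram(as.character(hyp$stage[ep0 + seq_len(n_ep)]))

  n_win <- length(mask)
  win_stage <- as.character(hyp_c$stage[floor((seq_len(n_win) - 1L) / 3) + 1L])

  observed <- intersect(STAGE_LEVELS, unique(win_stage))
  not_observed <- setdiff(STAGE_LEVELS, observed)

  bp_rows <- list(); comp_rows <- list(); untested <- character(0)
  for (st in observed) {
    st_mask <- mask | win_stage != st
    st_mask[is.na(st_mask)] <- TRUE
    n_clean <- sum(!st_mask)
    if (n_clean == 0L) { untested <- c(untested, st); next }
    bp_in <- relative_band_power(in_bb, fs, mask = st_mask, label = st)
    bp_sc <- relative_band_power(sc_bb, fs, mask = st_mask, label = st)
    bp_rows[[st]] <- rbind(
      data.frame(stage = st, device = "inear", bp_in,
                 n_windows = attr(bp_in, "n_windows")),
      data.frame(stage = st, device = "scalp", bp_sc,
                 n_windows = attr(bp_sc, "n_windows")))
    if (n_clean < min_windows) { untested <- c(untested, st); next }
    win_in <- attr(bp_in, "rsp_windows")
    win_sc <- attr(bp_sc, "rsp_windows")
    for (b in seq_len(nrow(bp_in))) {
      pt <- permutation_mean_diff_test(win_sc[b, ], win_in[b, ],
                                       n_perm = n_perm,
                                       seed = seed + 31L * b, alpha = alpha)
      comp_rows[[paste(st, b)]] <-
        data.frame(stage = st, band = bp_in$band[b],
                   mean_diff = pt$observed_stat, p = pt$p_two_sided)
    }
  }
  band_power <- do.call(rbind, c(bp_rows, list(make.row.names = FALSE)))
  band_comparison <- if (length(comp_rows) > 0) {
    bc <- do.call(rbind, c(comp_rows, list(make.row.names = FALSE)))
    fdr <- bh_fdr(bc$p, q)
    bc$p_adj <- fdr$adjusted
    bc$q_significant <- fdr$reject
    bc
  }

  stage_corr <- stage_correlations(in_bb, sc_bb, hyp_c, fs, mask = mask)
  stage_corr$agreement <- as.character(classify_agreement(stage_corr$mean_r))

  report <- list(
    protocol = "nap",
    alignment = pp$alignment,
    rms = data.frame(device = c("inear", "scalp"),
                     mean_uV = c(rms_in$summary["mean"], rms_sc$summary["mean"]),
                     sd_uV = c(rms_in$summary["sd"], rms_sc$summary["sd"]),
                     n_epochs = c(rms_in$summary["n"], rms_sc$summary["n"])),
    bad_data = data.frame(device = c("inear", "scalp"),
                          pct = c(bad_in$pct, bad_sc$pct),
                          exceeds_10pct = c(bad_in$exceeds_threshold,
                                            bad_sc$exceeds_threshold)),
    band_power = band_power,
    band_comparison = band_comparison,
    stage_correlations = stage_corr,
    not_observed = not_observed,
    untested = unique(untested),
    params = list(n_perm = n_perm, q = q, alpha = alpha, seed = seed,
                  min_windows = min_windows, epoch_len_s = 10,
                  amp_thresh_uV = 100, frac_thresh = 0.1))
  class(report) <- "study_report"
  write_report_csv(report$rms, out_dir, "rms_summary.csv")
  write_report_csv(report$bad_data, out_dir, "bad_data.csv")
  write_report_csv(report$band_power, out_dir, "band_power.csv")
  if (!is.null(band_comparison))
    write_report_csv(band_comparison, out_dir, "band_comparison.csv")
  write_report_csv(stage_corr, out_dir, "stage_correlations.csv")
  if (!is.null(out_dir))
    jsonlite::write_json(report$params, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %s>\n", x$protocol))
  cat(sprintf("  alignment offset: %.4f s (%d matched triggers)\n",
              x$alignment$offset_s, nrow(x$alignment$matched_triggers)))
  cat("  RMS (uV):\n"); print(x$rms)
  cat("  bad data (%):\n"); print(x$bad_data)
  if (!is.null(x$snr)) { cat("  SNR(alpha):\n"); print(x$snr) }
  if (!is.null(x$stage_correlations)) {
    cat("  stage correlations:\n"); print(x$stage_correlations)
  }
  invisible(x)
}
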
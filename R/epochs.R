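# Epoching, amplitude-threshold artifact flagging, RMS and bad-data stats.
#
# The quality rule: a 10-s epoch is rejected when the signal spends at
# least 10% of its samples outside +/-100 uV. Rejected epochs are excluded
# from every downstream statistic (RMS, SNR, band power, correlation);
# for paired device comparisons the union of both devices' flags is used
# so both sides are evaluated on identical time ranges.

#' Epoch a channel and flag artifact-contaminated epochs
#'
#' Tiles the recording into fixed-length non-overlapping epochs (trailing
#' partial epoch discarded) and flags an epoch as artifact iff the fraction
#' of samples with `|x| > amp_thresh_uV` is at least `frac_thresh`.
#'
#' @param rec an [eeg_recording()].
#' @param channel channel label or index.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @param amp_thresh_uV absolute amplitude threshold in microvolts
#'   (default 100).
#' @param frac_thresh flag when at least this fraction of samples exceeds
#'   the amplitude threshold (default 0.10).
#' @return an object of class `epoch_grid`: list with `epoch_len_s`, `fs`,
#'   `start_s` (epoch onsets on the recording's timeline), `index` (sample
#'   index matrix, epochs in columns), `artifact_flag`, `exceed_frac`
#'   (diagnostic per-epoch exceedance fraction), `channel`, `signal`.
#' @export
epoch_and_flag <- function(rec, channel = 1L, epoch_len_s = 10,
                           amp_thresh_uV = 100, frac_thresh = 0.10) {
  stopifnot(inherits(rec, "eeg_recording"),
            amp_thresh_uV > 0, frac_thresh > 0, frac_thresh < 1)
  spe <- round(epoch_len_s * rec$fs)
  if (spe < 1) stop("epoch_len_s x fs must be >= 1")
  x <- get_channel(rec, channel)
  n_ep <- floor(length(x) / spe)
  if (n_ep < 1L) stop("recording shorter than one epoch")
  idx <- matrix(seq_len(n_ep * spe), nrow = spe)
  exceed <- colMeans(matrix(abs(x[idx]) > amp_thresh_uV, nrow = spe))
  structure(
    list(epoch_len_s = epoch_len_s, fs = rec$fs,
         start_s = rec$start_offset_s + (seq_len(n_ep) - 1L) * epoch_len_s,
         index = idx,
         artifact_flag = exceed >= frac_thresh,
         exceed_frac = exceed,
         channel = if (is.character(channel)) channel
                   else colnames(rec$data)[channel],
         signal = x),
    class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d x %g-s epochs on '%s'; %d flagged (%.1f%%)\n",
              length(x$artifact_flag), x$epoch_len_s, x$channel,
              sum(x$artifact_flag), 100 * mean(x$artifact_flag)))
  invisible(x)
}

#' Per-epoch RMS and summary
#'
#' Root-mean-square amplitude per retained epoch, with mean, SD and range
#' across epochs. Flagged epochs are excluded by default.
#'
#' @param grid an `epoch_grid` from [epoch_and_flag()].
#' @param include_flagged keep artifact epochs too? Default `FALSE`.
#' @return list with `rms` (data.frame: epoch start, RMS in microvolts,
#'   flag) over retained epochs and `summary` (mean, sd, min, max, n). When
#'   every epoch is flagged, `status` is `"no clean data"` and the summary
#'   is all `NA`.
#' @export
rms_per_epoch <- function(grid, include_flagged = FALSE) {
  stopifnot(inherits(grid, "epoch_grid"))
  rms_all <- sqrt(colMeans(matrix(grid$signal[grid$index]^2,
                                  nrow = nrow(grid$index))))
  keep <- if (include_flagged) rep(TRUE, length(rms_all)) else !grid$artifact_flag
  df <- data.frame(start_s = grid$start_s[keep], rms_uV = rms_all[keep],
                   artifact = grid$artifact_flag[keep])
  if (nrow(df) == 0L) {
    return(list(rms = df,
                summary = c(mean = NA_real_, sd = NA_real_,
                            min = NA_real_, max = NA_real_, n = 0),
                status = "no clean data"))
  }
  list(rms = df,
       summary = c(mean = mean(df$rms_uV), sd = stats::sd(df$rms_uV),
                   min = min(df$rms_uV), max = max(df$rms_uV),
                   n = nrow(df)),
       status = "ok")
}

#' Percentage of artifact-flagged (bad) epochs
#'
#' @param grid an `epoch_grid`.
#' @param quality_thresh_pct recordings with strictly more than this
#'   percentage of bad epochs fail the quality verdict (default 10).
#' @return list with `pct` (0-100) and `exceeds_threshold` (strict `>`).
#' @export
bad_data_fraction <- function(grid, quality_thresh_pct = 10) {
  stopifnot(inherits(grid, "epoch_grid"))
  pct <- 100 * mean(grid$artifact_flag)
  list(pct = pct, exceeds_threshold = pct > quality_thresh_pct)
}

#' Shared clean-epoch mask for a device pair
#'
#' Union of two grids' artifact flags, so paired statistics compare
#' identical time ranges on both devices.
#'
#' @param gridA,gridB `epoch_grid`s with equal epoch counts and lengths.
#' @return logical vector, `TRUE` where either device is flagged.
#' @export
shared_artifact_mask <- function(gridA, gridB) {
  stopifnot(length(gridA$artifact_flag) == length(gridB$artifact_flag),
            gridA$epoch_len_s == gridB$epoch_len_s)
  gridA$artifact_flag | gridB$artifact_flag
}
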
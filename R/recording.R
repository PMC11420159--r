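#' Multichannel EEG recording
#'
#' Container for a labeled multichannel time series in microvolts, with a
#' sampling rate, an optional dedicated trigger channel, and a start offset
#' on a shared experiment timeline. All channels share length and sampling
#' rate; sample values must be finite.
#'
#' @param data numeric matrix, samples in rows, one column per channel, in
#'   microvolts. Column names are the channel labels (10-10 names for scalp
#'   montages, anything for the in-ear channel).
#' @param fs sampling rate in Hz (> 0).
#' @param trigger optional numeric vector, same length as the data, holding
#'   the synchronization pulse train.
#' @param start_offset_s start time of sample 0 on the common timeline, in
#'   seconds. Alignment rewrites this field.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, trigger = NULL, start_offset_s = 0) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L, dimnames = list(NULL, "ch1"))
  stopifnot(is.matrix(data), is.numeric(data), nrow(data) >= 1L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (!all(is.finite(data))) stop("sample values must be finite")
  if (is.null(colnames(data)))
    colnames(data) <- paste0("ch", seq_len(ncol(data)))
  if (!is.null(trigger)) {
    stopifnot(is.numeric(trigger), length(trigger) == nrow(data))
    if (!all(is.finite(trigger))) stop("trigger values must be finite")
  }
  structure(
    list(data = data, fs = fs, trigger = trigger,
         start_offset_s = start_offset_s),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(utils::head(colnames(x$data), 8), collapse = ", "),
      if (ncol(x$data) > 8) "..." else "", "\n")
  cat(sprintf("  trigger: %s; start offset %.4f s\n",
              if (is.null(x$trigger)) "none" else "present", x$start_offset_s))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) nrow(rec$data) / rec$fs

#' Extract one channel as a numeric vector
#' @param rec an `eeg_recording`.
#' @param channel channel label (column name) or column index.
#' @return numeric vector of samples in microvolts.
#' @export
get_channel <- function(rec, channel) {
  if (is.character(channel) && !channel %in% colnames(rec$data))
    stop(sprintf("channel '%s' not found", channel))
  rec$data[, channel]
}

#' Crop a recording to a sample range
#' @param rec an `eeg_recording`.
#' @param from,to 1-based first and last sample to keep.
#' @return cropped `eeg_recording`; `start_offset_s` advances accordingly.
#' @export
crop_samples <- function(rec, from, to) {
  stopifnot(from >= 1, to <= nrow(rec$data), from <= to)
  eeg_recording(rec$data[from:to, , drop = FALSE], rec$fs,
                trigger = if (!is.null(rec$trigger)) rec$trigger[from:to],
                start_offset_s = rec$start_offset_s + (from - 1) / rec$fs)
}

#' Write / read a recording as plain-text CSV
#'
#' The first column is the trigger channel (all zeros when absent), the
#' remaining columns the data channels. Sampling rate and start offset are
#' stored in a `# fs=<Hz> start_offset_s=<s>` header comment so the file is
#' self-describing.
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g start_offset_s=%.10g", rec$fs,
                     rec$start_offset_s), con)
  trig <- if (is.null(rec$trigger)) numeric(nrow(rec$data)) else rec$trigger
  df <- data.frame(trigger = trig, rec$data, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("fs=([0-9.eE+-]+) start_offset_s=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3L) stop("missing '# fs=... start_offset_s=...' header")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  trig <- df[["trigger"]]
  dat <- as.matrix(df[, setdiff(names(df), "trigger"), drop = FALSE])
  eeg_recording(dat, fs = as.numeric(m[2]),
                trigger = if (any(trig != 0)) trig,
                start_offset_s = as.numeric(m[3]))
}
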
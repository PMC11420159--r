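# Trigger detection and dual-device alignment.
#
# Both acquisition systems receive the same hardware pulse train on a
# dedicated trigger channel but run on independent clocks, so the two
# records start at different times and may drift apart slowly. Alignment
# detects pulse onsets in each record, pairs them, and removes the constant
# offset; any residual (drift) is reported so downstream correlation can
# budget for it via the lag-tolerant search.

#' Detect trigger pulse onsets
#'
#' Finds onsets of excursions where the absolute trigger trace crosses a
#' fraction of its own maximum. Consecutive supra-threshold crossings
#' within the refractory window collapse to a single event, so a
#' rectangular pulse yields one onset.
#'
#' @param trace numeric trigger trace.
#' @param fs sampling rate in Hz.
#' @param threshold detection level as a fraction of `max(abs(trace))`,
#'   in (0, 1). Default 0.5.
#' @param refractory_s minimum separation between distinct events, in
#'   seconds. Default 0.2.
#' @return numeric vector of onset times in seconds (0-based sample times).
#'   An all-zero (or empty) trace returns `numeric(0)` — the "missing
#'   triggers" failure mode that makes synchronization impossible.
#' @export
detect_triggers <- function(trace, fs, threshold = 0.5, refractory_s = 0.2) {
  stopifnot(all(is.finite(trace)), fs > 0,
            threshold > 0, threshold < 1)
  a <- abs(trace)
  peak <- max(a)
  if (length(trace) == 0L || peak == 0) return(numeric(0))
  above <- a >= threshold * peak
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  if (length(onsets) == 0L) return(numeric(0))
  keep <- onsets[1]
  gap <- round(refractory_s * fs)
  for (o in onsets[-1]) if (o - keep[length(keep)] > gap) keep <- c(keep, o)
  (keep - 1) / fs
}

#' Align two simultaneously recorded devices by their trigger trains
#'
#' Estimates the clock offset between two recordings from matched trigger
#' events and re-times the second recording so paired events coincide. The
#' offset is the median of paired event-time differences (robust to a
#' missed pulse); pairing is greedy nearest-neighbor after anchoring on the
#' first event of each train. Per-pair residuals after offset removal
#' expose any remaining inter-clock drift.
#'
#' @param recA,recB [eeg_recording()]s carrying trigger channels.
#' @param threshold,refractory_s passed to [detect_triggers()].
#' @param max_pair_gap_s events farther apart than this after first-event
#'   anchoring are left unmatched (default 5 s).
#' @return list with `offset_s` (device B start minus device A start, i.e.
#'   the amount B must be advanced), `matched_triggers` (data.frame of
#'   paired times), `residual_s` (per-pair residual after offset removal),
#'   and `recB_aligned` (B with `start_offset_s` rewritten so its events
#'   land on A's timeline).
#' @export
align_pair <- function(recA, recB, threshold = 0.5, refractory_s = 0.2,
                       max_pair_gap_s = 5) {
  stopifnot(inherits(recA, "eeg_recording"), inherits(recB, "eeg_recording"))
  if (is.null(recA$trigger) || is.null(recB$trigger))
    stop("both recordings need a trigger channel for alignment")
  tA <- detect_triggers(recA$trigger, recA$fs, threshold, refractory_s) +
    recA$start_offset_s
  tB <- detect_triggers(recB$trigger, recB$fs, threshold, refractory_s) +
    recB$start_offset_s
  if (length(tA) == 0L || length(tB) == 0L)
    stop("synchronization impossible: no detectable trigger events ",
         "(missing triggers)")
  if (length(tA) != length(tB))
    warning(sprintf("unequal trigger counts (%d vs %d); pairing on overlap",
                    length(tA), length(tB)))
  # anchor on first events, then greedy nearest-neighbor pairing
  anchor <- tB[1] - tA[1]
  pairs <- lapply(tA, function(t) {
    d <- abs(tB - anchor - t)
    j <- which.min(d)
    if (d[j] <= max_pair_gap_s) c(t, tB[j]) else NULL
  })
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("synchronization impossible: no trigger events could be paired")
  diffs <- pairs[, 2] - pairs[, 1]
  offset <- stats::median(diffs)
  recB2 <- recB
  recB2$start_offset_s <- recB$start_offset_s - offset
  list(offset_s = offset,
       matched_triggers = data.frame(time_A_s = pairs[, 1],
                                     time_B_s = pairs[, 2]),
       residual_s = diffs - offset,
       recB_aligned = recB2)
}

#' Crop two aligned recordings to their common timeline
#'
#' After [align_pair()] the two recordings share a timeline but may start
#' and end at different times. This trims both to the overlapping interval
#' so sample `i` of each (at a common rate) refers to the same instant.
#'
#' @param recA,recB aligned [eeg_recording()]s (same `fs`).
#' @return list of the two cropped recordings.
#' @export
crop_to_overlap <- function(recA, recB) {
  stopifnot(recA$fs == recB$fs)
  fs <- recA$fs
  t0 <- max(recA$start_offset_s, recB$start_offset_s)
  t1 <- min(recA$start_offset_s + rec_duration(recA),
            recB$start_offset_s + rec_duration(recB))
  if (t1 <= t0) stop("recordings do not overlap in time")
  cut <- function(r) {
    from <- 1L + round((t0 - r$start_offset_s) * fs)
    n <- floor((t1 - t0) * fs)
    crop_samples(r, from, from + n - 1L)
  }
  list(cut(recA), cut(recB))
}
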
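# Hypnograms: 30-s sleep-stage labels aligned to a recording. Staging
# itself is out of scope — hypnograms are consumed as input (or produced
# by the nap generator).

STAGE_LEVELS <- c("Wake", "N1", "N2", "N3", "REM")

#' Hypnogram of 30-s sleep-stage labels
#'
#' @param stages character vector of stage labels, one per 30-s epoch, in
#'   `{Wake, N1, N2, N3, REM}`.
#' @param epoch_len_s epoch length in seconds (fixed at 30 by convention).
#' @return data.frame of class `hypnogram` with 0-based `epoch` and
#'   factor `stage`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30) {
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad) > 0)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(epoch = seq_along(stages) - 1L,
                    stage = factor(stages, levels = STAGE_LEVELS))
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("hypnogram", class(out))
  out
}

#' Read / write a hypnogram as two-column CSV
#'
#' Columns `epoch` (0-based index) and `stage`.
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @return `write_hypnogram_csv` returns `path` invisibly;
#'   `read_hypnogram_csv` returns a `hypnogram`.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  utils::write.csv(data.frame(epoch = hyp$epoch,
                              stage = as.character(hyp$stage)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch", "stage") %in% names(df)))
    stop("hypnogram CSV needs 'epoch' and 'stage' columns")
  hypnogram(df$stage[order(df$epoch)])
}
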
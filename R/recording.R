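# Core containers: recording, hypnogram, arousal event table.

#' Sleep stage alphabet
#'
#' The five stage symbols used throughout: wake, the three non-REM depths and
#' REM, scored in 30-second epochs.
#' @export
STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Construct a multichannel recording
#'
#' @param channels Named list of equal-length numeric vectors (volts).
#' @param fs Sampling rate in Hz.
#' @param start_time Seconds origin (0 by convention).
#' @return An object of class `psg_recording`.
#' @export
psg_recording <- function(channels, fs, start_time = 0) {
  stopifnot(is.list(channels), length(channels) >= 1L, fs > 0)
  labels <- names(channels)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == "")) {
    stop("channels must be a uniquely named list")
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all channels must have equal length")
  structure(list(channels = channels, fs = fs, start_time = start_time,
                 duration = lens[[1L]] / fs),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channels (%s), fs = %g Hz, %.1f s\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$fs, x$duration))
  invisible(x)
}

n_samples <- function(recording) length(recording$channels[[1L]])

#' Construct a hypnogram
#'
#' @param labels Character vector of stage symbols over [STAGES], one per epoch.
#' @param epoch_length Epoch length in seconds (30 by convention).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_length = 30) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), STAGES)
  if (length(bad)) {
    stop("unknown stage symbol(s): ", paste(bad, collapse = ", "))
  }
  structure(list(labels = labels, epoch_length = epoch_length),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s (%s)\n", length(x$labels),
              x$epoch_length,
              paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Stage at a time point
#'
#' Looks up the hypnogram epoch containing time `t` (epoch index =
#' `floor(t / epoch_length)`, 0-based).
#'
#' @param hyp A [hypnogram()].
#' @param t Time(s) in seconds from recording start.
#' @return Character vector of stage symbols.
#' @export
stage_at <- function(hyp, t) {
  idx <- pmin(floor(t / hyp$epoch_length) + 1L, length(hyp$labels))
  if (any(t < 0)) stop("time must be non-negative")
  hyp$labels[idx]
}

#' Construct an arousal event table
#'
#' Events are rows of a data frame with half-open windows
#' `[onset, onset + duration)` in seconds from recording start. Non-sham
#' events must last at least 3 s (the arousal definition); sham events are
#' stable-sleep control windows scored as intensity level 0.
#'
#' @param onset Numeric vector of onsets (s).
#' @param duration Numeric vector of durations (s).
#' @param stage Stage symbol at onset (optional, filled by [read_annotations()]
#'   or [stage_at()]).
#' @param is_sham Logical vector, default `FALSE`.
#' @return A data frame of class `arousal_events`, sorted by onset.
#' @export
arousal_events <- function(onset = numeric(), duration = numeric(),
                           stage = rep(NA_character_, length(onset)),
                           is_sham = rep(FALSE, length(onset))) {
  if (length(onset) && (any(onset < 0) || any(duration <= 0))) {
    stop("onsets must be >= 0 and durations > 0")
  }
  if (length(onset) && any(!is_sham & duration < 3)) {
    stop("non-sham arousal events must last at least 3 s")
  }
  df <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   stage = as.character(stage), is_sham = as.logical(is_sham),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("arousal_events", "data.frame")
  df
}
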
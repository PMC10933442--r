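# Automatic arousal-intensity scoring: peak-to-peak amplitude distance on the
# central EEG channels, quartile binning into levels 1-4, and selection of
# sham (level-0) stable-sleep control windows.

#' Amplitude distance of one event
#'
#' The intensity measure: the mean over the raw C3 and C4 channels of the
#' peak-to-peak (max minus min) amplitude within the arousal window.
#'
#' @param pair A `segment_pair` from [extract_segment_pair()] containing raw
#'   `C3` and `C4` arousal segments.
#' @return Amplitude distance in volts (non-negative scalar).
#' @export
amplitude_distance <- function(pair) {
  need <- setdiff(c("C3", "C4"), names(pair$arousal))
  if (length(need)) stop("segment pair lacks raw channel(s): ",
                         paste(need, collapse = ", "))
  ranges <- vapply(c("C3", "C4"), function(ch) {
    x <- pair$arousal[[ch]]
    if (!length(x)) stop("empty arousal segment for channel ", ch)
    max(x) - min(x)
  }, numeric(1))
  mean(ranges)
}

#' Quartile binning thresholds
#'
#' Fits the level edges from a set of amplitude distances: `q1`/`q2`/`q3` are
#' the 25th/50th/75th percentiles (linear-interpolation quantile), and the
#' outer edges extend slightly beyond the observed min/max so every fitted
#' value falls into a level.
#'
#' @param amplitudes Numeric vector of amplitude distances (volts), at least
#'   8 distinct values.
#' @return A list of class `binning_thresholds` with `lower_edge`, `q1`,
#'   `q2`, `q3`, `upper_edge`.
#' @export
fit_quartile_thresholds <- function(amplitudes) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(unique(amplitudes)) < 8L) {
    stop("need at least 8 distinct amplitudes to fit quartile thresholds")
  }
  if (diff(range(amplitudes)) == 0) stop("degenerate amplitude distribution")
  q <- stats::quantile(amplitudes, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  span <- diff(range(amplitudes))
  binning_thresholds(lower_edge = min(amplitudes) - 1e-3 * span,
                     q1 = q[1L], q2 = q[2L], q3 = q[3L],
                     upper_edge = max(amplitudes) + 1e-3 * span)
}

#' @rdname fit_quartile_thresholds
#' @param lower_edge,q1,q2,q3,upper_edge Edges in volts, strictly increasing.
#' @export
binning_thresholds <- function(lower_edge, q1, q2, q3, upper_edge) {
  edges <- c(lower_edge, q1, q2, q3, upper_edge)
  if (any(diff(edges) <= 0)) stop("threshold edges must be strictly increasing")
  structure(list(lower_edge = lower_edge, q1 = q1, q2 = q2, q3 = q3,
                 upper_edge = upper_edge), class = "binning_thresholds")
}

#' Reference binning thresholds
#'
#' The fixed reference level edges shipped with the package (intervals in
#' volts: (-0.001, 9.3e-5], (9.3e-5, 1.64e-4], (1.64e-4, 4.04e-4],
#' (4.04e-4, 6.03e-3]). These edges are cohort-specific; fitting thresholds
#' from the data at hand ([fit_quartile_thresholds()]) is the default mode.
#'
#' @return A `binning_thresholds` object.
#' @export
reference_thresholds <- function() {
  path <- system.file("extdata", "reference_thresholds.json",
                      package = "arousalint")
  th <- jsonlite::read_json(path, simplifyVector = TRUE)
  binning_thresholds(th$lower_edge, th$q1, th$q2, th$q3, th$upper_edge)
}

#' Assign an intensity level to one amplitude
#'
#' Sham events are level 0 regardless of amplitude. Other events fall into
#' right-closed intervals: `(lower, q1] -> 1`, `(q1, q2] -> 2`,
#' `(q2, q3] -> 3`, `(q3, upper] -> 4`. Amplitudes beyond the outer edges are
#' clamped to level 1 or 4 with a warning.
#'
#' @param amplitude Amplitude distance in volts (non-negative).
#' @param thresholds A `binning_thresholds` object.
#' @param is_sham Whether the event is a sham (stable-sleep) control.
#' @return Integer level 0-4.
#' @export
assign_level <- function(amplitude, thresholds, is_sham = FALSE) {
  if (is_sham) return(0L)
  if (is.na(amplitude) || amplitude < 0) {
    stop("amplitude distance must be non-negative")
  }
  edges <- c(thresholds$lower_edge, thresholds$q1, thresholds$q2,
             thresholds$q3, thresholds$upper_edge)
  if (amplitude <= edges[1L]) {
    warning("amplitude below the lower edge; clamped to level 1")
    return(1L)
  }
  if (amplitude > edges[5L]) {
    warning("amplitude above the upper edge; clamped to level 4")
    return(4L)
  }
  # right-closed: (edges[k], edges[k+1]] -> k
  as.integer(findInterval(amplitude, edges, left.open = TRUE,
                          rightmost.closed = TRUE))
}

#' Select sham (level-0) stable-sleep windows
#'
#' Draws, per recording, a uniform count in `{sham_min, ..., sham_max}` of
#' non-overlapping windows of `sham_len_s` seconds, each lying entirely
#' within non-wake epochs and at least `clearance_s` seconds away from every
#' arousal boundary and from every other selected window. When eligible sleep
#' is insufficient, fewer windows are returned with a warning.
#'
#' @param hyp A [hypnogram()].
#' @param events An [arousal_events()] table for the same recording.
#' @param seed Integer seed for the draw.
#' @param sham_min,sham_max Count range (defaults 10 and 14).
#' @param sham_len_s Window length in seconds (default 9).
#' @param clearance_s Required distance from arousal boundaries (default 10).
#' @return An [arousal_events()] table of sham events (possibly empty).
#' @export
select_sham_windows <- function(hyp, events, seed = 1L, sham_min = 10L,
                                sham_max = 14L, sham_len_s = 9,
                                clearance_s = 10) {
  set.seed(seed)
  target <- sample(sham_min:sham_max, 1L)
  total_s <- length(hyp$labels) * hyp$epoch_length
  grid <- seq(sham_len_s, total_s - sham_len_s, by = 1)   # candidate onsets
  ok <- vapply(grid, function(on) {
    win <- c(on - clearance_s, on + sham_len_s + clearance_s)
    ep <- floor(c(on, on + sham_len_s - 1e-9) / hyp$epoch_length) + 1L
    if (any(hyp$labels[ep[1L]:ep[2L]] == "W")) return(FALSE)
    if (nrow(events)) {
      clash <- events$onset < win[2L] & (events$onset + events$duration) > win[1L]
      if (any(clash)) return(FALSE)
    }
    TRUE
  }, logical(1))
  grid <- grid[ok]
  chosen <- numeric(0)
  while (length(chosen) < target && length(grid)) {
    on <- grid[sample.int(length(grid), 1L)]
    chosen <- c(chosen, on)
    grid <- grid[abs(grid - on) >= sham_len_s + clearance_s]
  }
  if (length(chosen) < target) {
    warning(sprintf("only %d of %d sham windows could be placed",
                    length(chosen), target))
  }
  if (!length(chosen)) return(arousal_events())
  ev <- arousal_events(onset = sort(chosen),
                       duration = rep(sham_len_s, length(chosen)),
                       is_sham = rep(TRUE, length(chosen)))
  ev$stage <- stage_at(hyp, ev$onset)
  ev
}

#' Score a recording's events with amplitude distances and intensity levels
#'
#' Measures the amplitude distance of every event on the preprocessed
#' recording, fits or applies binning thresholds, and assigns levels
#' (0 for shams). Events whose segment pair cannot be extracted are dropped.
#'
#' @param recording A preprocessed [psg_recording()] containing C3 and C4.
#' @param events An [arousal_events()] table (real plus sham events).
#' @param thresholds `NULL` to fit quartile thresholds from the non-sham
#'   amplitudes at hand (the default procedure), or a `binning_thresholds`
#'   object (e.g. [reference_thresholds()]) to apply fixed edges.
#' @param composite_map See [default_composite_map()].
#' @return The events table with `amplitude` and `level` columns, carrying
#'   the thresholds used as attribute `"thresholds"`.
#' @export
score_events <- function(recording, events, thresholds = NULL,
                         composite_map = default_composite_map()) {
  out <- measure_amplitudes(recording, events, composite_map)
  if (is.null(thresholds)) {
    thresholds <- fit_quartile_thresholds(out$amplitude[!out$is_sham])
  }
  out$level <- vapply(seq_len(nrow(out)), function(i) {
    assign_level(out$amplitude[i], thresholds, is_sham = out$is_sham[i])
  }, integer(1))
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  out
}

#' Measure amplitude distances without assigning levels
#'
#' The measurement half of [score_events()]: extracts each event's segment
#' pair and records its amplitude distance, dropping events whose pre-window
#' falls outside the recording. Used when thresholds are to be fitted
#' globally over several recordings before levels are assigned.
#'
#' @inheritParams score_events
#' @return The events table (retained rows only) with an `amplitude` column.
#' @export
measure_amplitudes <- function(recording, events,
                               composite_map = default_composite_map()) {
  keep <- logical(nrow(events))
  amps <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    pair <- withCallingHandlers(
      extract_segment_pair(recording, events[i, ], composite_map),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(pair)) next
    keep[i] <- TRUE
    amps[i] <- amplitude_distance(pair)
  }
  out <- events[keep, , drop = FALSE]
  out$amplitude <- amps[keep]
  rownames(out) <- NULL
  out
}
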
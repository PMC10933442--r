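# Synthetic polysomnography: stage-profiled colored-noise EEG/EMG, a Markov
# hypnogram, injected arousal bursts with controllable amplitude strata, and
# per-event ground truth so downstream recovery can be tested.

.default_transition <- function() {
  m <- rbind(W   = c(0.50, 0.45, 0.05, 0.00, 0.00),
             N1  = c(0.05, 0.40, 0.45, 0.00, 0.10),
             N2  = c(0.03, 0.05, 0.72, 0.12, 0.08),
             N3  = c(0.00, 0.00, 0.25, 0.75, 0.00),
             REM = c(0.02, 0.08, 0.10, 0.00, 0.80))
  colnames(m) <- STAGES
  m
}

.default_spectra <- function() {
  # relative band weights (delta/theta/alpha/beta) and total RMS in volts
  # RMS levels sit well below the event amplitude law so that the measured
  # peak-to-peak of an event window is dominated by the injected burst, as in
  # the scored-amplitude regime the reference interval edges describe
  list(W   = list(weights = c(delta = 0.15, theta = 0.20, alpha = 0.40, beta = 0.25), rms = 1.0e-5),
       N1  = list(weights = c(delta = 0.30, theta = 0.40, alpha = 0.20, beta = 0.10), rms = 0.9e-5),
       N2  = list(weights = c(delta = 0.45, theta = 0.35, alpha = 0.12, beta = 0.08), rms = 1.0e-5),
       N3  = list(weights = c(delta = 0.70, theta = 0.20, alpha = 0.06, beta = 0.04), rms = 1.4e-5),
       REM = list(weights = c(delta = 0.25, theta = 0.35, alpha = 0.20, beta = 0.20), rms = 0.7e-5))
}

#' Synthetic polysomnography configuration
#'
#' Defaults emulate the data regime the pipeline targets: overnight-scale
#' recordings at 200 Hz with seven channels, roughly 30 arousals per hour of
#' sleep, and event peak-to-peak amplitudes on the order of 1e-4 V drawn from
#' a log-normal law whose quartiles define four ground-truth strata.
#'
#' `class_separation` controls how distinct the strata are: amplitudes are
#' drawn by mapping a within-stratum uniform sub-quantile, compressed toward
#' the stratum-center quantile by `1/class_separation`, through the law.
#' A value of 1 reproduces the plain law; large values open gaps at the
#' quartile edges so the strata become essentially disjoint.
#'
#' @param n_recordings Number of recordings (default 8).
#' @param duration Recording length in seconds (default 5400; minimum 60).
#' @param fs Sampling rate in Hz (default 200).
#' @param seed Integer seed.
#' @param stage_transition 5x5 row-stochastic matrix over `W,N1,N2,N3,REM`.
#' @param stage_spectra Per-stage list of band `weights`
#'   (delta/theta/alpha/beta) and background `rms` (volts).
#' @param arousal_rate Events per hour (default 32).
#' @param amplitude_law List `meanlog`, `sdlog` of the log-normal event
#'   amplitude law (volts peak-to-peak).
#' @param class_separation Stratum-distinctness multiplier (default 1).
#' @param event_duration_range Event duration range in seconds
#'   (default `c(3, 15)`; minimum duration 3 s).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_recordings = 8L, duration = 5400, fs = 200,
                             seed = 1L,
                             stage_transition = .default_transition(),
                             stage_spectra = .default_spectra(),
                             arousal_rate = 32,
                             amplitude_law = list(meanlog = log(1.8e-4),
                                                  sdlog = 0.9),
                             class_separation = 1,
                             event_duration_range = c(3, 15)) {
  if (fs <= 0) stop("fs must be positive")
  if (duration < 60) stop("duration must be at least 60 s")
  if (event_duration_range[1L] < 3) {
    stop("event durations must be at least 3 s (arousal definition)")
  }
  stage_transition <- as.matrix(stage_transition)
  if (!all(dim(stage_transition) == c(5L, 5L)) ||
      any(stage_transition < 0) ||
      any(abs(rowSums(stage_transition) - 1) > 1e-12)) {
    stop("stage_transition must be a 5x5 row-stochastic matrix")
  }
  if (class_separation < 1) stop("class_separation must be >= 1")
  structure(list(n_recordings = n_recordings, duration = duration, fs = fs,
                 seed = as.integer(seed), stage_transition = stage_transition,
                 stage_spectra = stage_spectra, arousal_rate = arousal_rate,
                 amplitude_law = amplitude_law,
                 class_separation = class_separation,
                 event_duration_range = event_duration_range),
            class = "synthetic_config")
}

#' Sample a hypnogram from the stage-transition chain
#'
#' A first-order Markov chain over the five stages in 30-s epochs, starting
#' in wake (recordings begin before sleep onset); `ceiling(duration / 30)`
#' epochs.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [hypnogram()].
#' @export
sample_hypnogram <- function(config, seed = config$seed) {
  set.seed(seed)
  n_ep <- ceiling(config$duration / 30)
  P <- config$stage_transition
  labels <- character(n_ep)
  labels[1L] <- "W"
  for (i in seq_len(n_ep - 1L)) {
    labels[i + 1L] <- sample(STAGES, 1L, prob = P[labels[i], ])
  }
  hypnogram(labels)
}

.band_edges <- list(delta = c(0.5, 4), theta = c(4, 8),
                    alpha = c(8, 13), beta = c(13, 30))

# unit-RMS band-limited Gaussian noise of length n at rate fs
.band_noise <- function(n, fs, band) {
  bt <- signal::butter(2, pmin(band, fs / 2 - 1e-6) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bt, stats::rnorm(n)))
  x / stats::sd(x)
}

# draw event amplitudes: balanced strata, within-stratum sub-quantile
# compressed toward the stratum center by 1/class_separation
.draw_amplitudes <- function(n, law, separation) {
  # balanced strata; the off-multiple remainder is drawn at random so pooled
  # counts stay near-balanced across recordings
  strata <- c(rep(1:4, n %/% 4L), sample(1:4, n %% 4L))
  strata <- if (n > 0L) sample(strata) else integer(0)
  w <- stats::runif(n)
  u <- (strata - 0.5) / 4 + 0.25 * (w - 0.5) / separation
  u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
  list(strata = strata,
       amplitude = stats::qlnorm(u, meanlog = law$meanlog, sdlog = law$sdlog))
}

.raised_cosine_ramp <- function(len, fs, ramp_s = 0.5) {
  env <- rep(1, len)
  r <- min(round(ramp_s * fs), len %/% 2L)
  if (r > 0L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[(len - r + 1L):len] <- rev(ramp)
  }
  env
}

#' Generate one synthetic recording with arousal events and ground truth
#'
#' Background EEG is a per-stage weighted sum of band-limited Gaussian noise
#' (delta-heavy in N3, low-voltage mixed-frequency in REM), scaled to the
#' stage RMS; each arousal is an additive 8-30 Hz noise burst with 0.5-s
#' raised-cosine on/off ramps, scaled so the peak-to-peak of the injected
#' component on every EEG channel equals the drawn amplitude (the chin EMG
#' burst is injected at half scale). Events are placed by seeded rejection
#' sampling where at least 10 s of non-wake, event-free signal precedes the
#' onset, the pre-window fits inside the recording, and events never overlap.
#' When the requested rate cannot be honoured under those constraints, fewer
#' events are emitted with a warning.
#'
#' @param config A [synthetic_config()].
#' @param hyp A [hypnogram()] covering the duration (default: freshly
#'   sampled).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param keep_background Keep a copy of the pre-injection background
#'   channels (element `background`) so the injected burst component can be
#'   recovered as signal minus background (default `FALSE`).
#' @return A list with `recording` (a 7-channel [psg_recording()]),
#'   `events` (an [arousal_events()] table) and `ground_truth` (a data frame
#'   with one row per injected event: onset, duration, stage, stratum 1-4,
#'   amplitude in volts).
#' @export
generate_recording <- function(config, hyp = sample_hypnogram(config, seed),
                               seed = config$seed, keep_background = FALSE) {
  set.seed(seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  ch_names <- c("C3", "C4", "O1", "O2", "F3", "F4", "chin")

  # per-sample stage index and per-band weight envelopes
  ep_of_sample <- pmin(floor((seq_len(n) - 1L) / (30 * fs)) + 1L,
                       length(hyp$labels))
  stage_seq <- hyp$labels[ep_of_sample]
  bands <- names(.band_edges)
  wmat <- vapply(STAGES, function(s) {
    w <- config$stage_spectra[[s]]$weights[bands]
    w / sqrt(sum(w^2)) * config$stage_spectra[[s]]$rms
  }, numeric(length(bands)))           # bands x stages, scaled to stage RMS
  stage_idx <- match(stage_seq, STAGES)

  channels <- stats::setNames(vector("list", length(ch_names)), ch_names)
  for (ch in ch_names) {
    x <- numeric(n)
    for (b in seq_along(bands)) {
      x <- x + wmat[b, stage_idx] * .band_noise(n, fs, .band_edges[[bands[b]]])
    }
    channels[[ch]] <- x
  }

  # event placement by rejection sampling
  hours <- config$duration / 3600
  target <- round(config$arousal_rate * hours)
  placed <- data.frame(onset = numeric(0), duration = numeric(0))
  tries <- 0L
  while (nrow(placed) < target && tries < 200L * max(target, 1L)) {
    tries <- tries + 1L
    d <- stats::runif(1, config$event_duration_range[1L],
                      config$event_duration_range[2L])
    on <- stats::runif(1, max(d, 10), config$duration - d)
    ep <- (floor((on - 10) / 30) + 1L):(floor((on + d - 1e-9) / 30) + 1L)
    if (any(hyp$labels[ep] == "W")) next
    if (nrow(placed)) {
      gap_ok <- placed$onset >= on + d + 10 |
        (placed$onset + placed$duration) <= on - 10
      if (!all(gap_ok)) next
    }
    placed <- rbind(placed, data.frame(onset = on, duration = d))
  }
  if (nrow(placed) < target) {
    warning(sprintf("placed %d of %d requested arousal events", nrow(placed),
                    target))
  }
  placed <- placed[order(placed$onset), , drop = FALSE]

  background <- if (keep_background) channels else NULL
  amp <- .draw_amplitudes(nrow(placed), config$amplitude_law,
                          config$class_separation)
  bt_burst <- signal::butter(4, c(8, 30) / (fs / 2), type = "pass")
  for (i in seq_len(nrow(placed))) {
    len <- round(placed$duration[i] * fs)
    i0 <- round(placed$onset[i] * fs)
    env <- .raised_cosine_ramp(len, fs)
    for (ch in ch_names) {
      burst <- as.numeric(signal::filter(bt_burst, stats::rnorm(len))) * env
      scale <- if (ch == "chin") 0.5 else 1
      burst <- burst / (max(burst) - min(burst)) * amp$amplitude[i] * scale
      sel <- (i0 + 1L):(i0 + len)
      channels[[ch]][sel] <- channels[[ch]][sel] + burst
    }
  }

  rec <- psg_recording(channels, fs = fs)
  if (nrow(placed)) {
    events <- arousal_events(onset = placed$onset, duration = placed$duration)
    events$stage <- stage_at(hyp, events$onset)
  } else {
    events <- arousal_events()
  }
  gt <- data.frame(onset = placed$onset, duration = placed$duration,
                   stage = if (nrow(placed)) stage_at(hyp, placed$onset)
                           else character(0),
                   stratum = amp$strata, amplitude = amp$amplitude)
  list(recording = rec, events = events, ground_truth = gt, hypnogram = hyp,
       background = background)
}

#' Simulate a dataset of synthetic recordings
#'
#' Generates `config$n_recordings` recordings with per-recording seeds
#' derived from `config$seed`, optionally writing each as EDF plus hypnogram
#' / events / ground-truth CSVs.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory, or `NULL` to keep everything in memory.
#' @return A list of per-recording lists as returned by
#'   [generate_recording()].
#' @export
simulate_psg_dataset <- function(config, out_dir = NULL) {
  out <- vector("list", config$n_recordings)
  for (i in seq_len(config$n_recordings)) {
    seed_i <- config$seed + 7919L * i
    hyp <- sample_hypnogram(config, seed = seed_i)
    out[[i]] <- generate_recording(config, hyp, seed = seed_i)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      base <- file.path(out_dir, sprintf("rec%02d", i))
      write_edf(out[[i]]$recording, paste0(base, ".edf"))
      write_hypnogram_csv(hyp, paste0(base, "_hypnogram.csv"))
      write_events_csv(out[[i]]$events, paste0(base, "_events.csv"))
      utils::write.csv(out[[i]]$ground_truth,
                       paste0(base, "_ground_truth.csv"), row.names = FALSE)
    }
  }
  out
}
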
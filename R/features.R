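# Assembly of the 136-dimensional pre-arousal-normalised feature vector:
# 33 wavelet statistics x 4 signals (C3/4, O1/2, F3/4, chin EMG) = 132,
# plus PSI, average power, RMS and the DFA exponent on C3/4 = 136.

.feature_signals <- c("C34", "O12", "F34", "chin")

.block_feature_names <- function() {
  sets <- .dwt_set_names
  pairs <- .mabs_ratio_pairs(sets)
  c(paste0("mpow_", sets), paste0("mabs_", sets),
    paste0("mabsratio_", pairs$num, "_", pairs$den), paste0("var_", sets))
}

#' Canonical feature names, in table column order
#'
#' 33 wavelet statistics per signal over the four signals `C34`, `O12`,
#' `F34`, `chin` (132 names), followed by the four auxiliary C3/4 features
#' `C34_psi`, `C34_avgpow`, `C34_rms`, `C34_dfa` (136 total). All values are
#' arousal / pre-arousal ratios.
#'
#' @return Character vector of length 136.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(.feature_signals, .block_feature_names(), paste,
                      sep = "_"))),
    paste0("C34_", c("psi", "avgpow", "rms", "dfa")))
}

#' Default power-spectral-intensity bands (Hz)
#'
#' Delta, theta, alpha, beta and low-gamma; bands are clipped at the Nyquist
#' frequency of the analysis rate.
#' @export
default_psi_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 60))
}

#' Auxiliary segment features: PSI, average power, RMS, DFA
#'
#' PSI is the mean over the configured bands of the summed periodogram power
#' inside each band; average power is the mean squared sample; RMS its square
#' root; DFA the scaling exponent of [dfa_exponent()]. Each is computed once
#' over the whole segment.
#'
#' @param segment Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param psi_bands Named list of `c(lo, hi)` band edges in Hz.
#' @return Named numeric vector `psi`, `avgpow`, `rms`, `dfa`.
#' @export
auxiliary_features <- function(segment, fs, psi_bands = default_psi_bands()) {
  if (!length(segment)) stop("empty segment")
  lo <- vapply(psi_bands, `[`, numeric(1), 1L)
  if (any(lo >= fs / 2)) {
    stop("PSI band starting at or above the Nyquist frequency ", fs / 2, " Hz")
  }
  n <- length(segment)
  p <- abs(stats::fft(segment))^2 / n          # periodogram (two-sided)
  freq <- (seq_len(n) - 1L) * fs / n
  half <- freq <= fs / 2
  psi <- mean(vapply(psi_bands, function(b) {
    hi <- min(b[2L], fs / 2)
    sum(p[half & freq >= b[1L] & freq < hi])
  }, numeric(1)))
  avgpow <- mean(segment^2)
  c(psi = psi, avgpow = avgpow, rms = sqrt(avgpow),
    dfa = dfa_exponent(segment))
}

.segment_features <- function(signals, fs, psi_bands, eps) {
  vals <- unlist(lapply(.feature_signals, function(sig) {
    block <- wavelet_feature_block(dwt_decompose(signals[[sig]]), eps = eps)
    stats::setNames(as.numeric(block), paste0(sig, "_", names(block)))
  }))
  aux <- auxiliary_features(signals[["C34"]], fs, psi_bands)
  c(vals, stats::setNames(as.numeric(aux), paste0("C34_", names(aux))))
}

#' Assemble the normalized 136-feature vector for one event
#'
#' Every feature is computed on the arousal segment and on the equally long
#' pre-arousal segment, and reported as the ratio arousal / pre-arousal;
#' denominators smaller than `eps` are floored at `eps` (flagged via the
#' `"guarded"` attribute). A vector containing non-finite values after the
#' guard signals an unusable event and raises an error (callers drop the
#' event and log the reason).
#'
#' @param pair A `segment_pair` from [extract_segment_pair()].
#' @param psi_bands PSI bands, see [default_psi_bands()].
#' @param eps Denominator floor (default 1e-24, far below any genuine
#'   feature magnitude in volt units, so the guard only ever fires on exact
#'   zeros).
#' @return Named numeric vector of length 136 in [feature_names()] order.
#' @export
assemble_normalized_vector <- function(pair, psi_bands = default_psi_bands(),
                                       eps = 1e-24) {
  need <- setdiff(.feature_signals, names(pair$arousal))
  if (length(need)) stop("segment pair lacks composite signal(s): ",
                         paste(need, collapse = ", "))
  fa <- .segment_features(pair$arousal, pair$fs, psi_bands, eps)
  fp <- .segment_features(pair$pre, pair$fs, psi_bands, eps)
  guarded <- any(abs(fp) < eps)
  out <- fa / ifelse(abs(fp) < eps, eps, fp)
  out <- out[feature_names()]
  if (any(!is.finite(out))) stop("non-finite feature value after epsilon guard")
  attr(out, "guarded") <- guarded
  out
}

#' Build the feature matrix for a set of scored events
#'
#' One row per retained event; events whose segment pair cannot be extracted
#' (pre-window out of bounds) or whose features are non-finite are dropped
#' and enumerated in the `"drop_log"` attribute with reasons.
#'
#' @param recording A preprocessed [psg_recording()].
#' @param scored_events An [arousal_events()] table with `amplitude` and
#'   `level` columns (see [score_events()]).
#' @param composite_map See [default_composite_map()].
#' @param psi_bands See [default_psi_bands()].
#' @param id_prefix Prefix for event ids (default `"ev"`).
#' @return Data frame with columns `event_id`, `stage`, `level` and the 136
#'   features, plus a `"drop_log"` attribute (data frame of id + reason).
#' @export
build_feature_matrix <- function(recording, scored_events,
                                 composite_map = default_composite_map(),
                                 psi_bands = default_psi_bands(),
                                 id_prefix = "ev") {
  rows <- list(); drops <- list()
  for (i in seq_len(nrow(scored_events))) {
    ev <- scored_events[i, ]
    id <- sprintf("%s%04d", id_prefix, i)
    pair <- withCallingHandlers(
      extract_segment_pair(recording, ev, composite_map),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(pair)) {
      drops[[length(drops) + 1L]] <- data.frame(event_id = id,
                                                reason = "pre-window out of bounds")
      next
    }
    fv <- tryCatch(assemble_normalized_vector(pair, psi_bands),
                   error = function(e) e)
    if (inherits(fv, "error")) {
      drops[[length(drops) + 1L]] <- data.frame(event_id = id,
                                                reason = conditionMessage(fv))
      next
    }
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(event_id = id, stage = ev$stage, level = ev$level,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(fv)))
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), 136L), feature_names()))
    cbind(data.frame(event_id = character(0), stage = character(0),
                     level = integer(0)), empty)
  }
  rownames(out) <- NULL
  attr(out, "drop_log") <- if (length(drops)) do.call(rbind, drops) else
    data.frame(event_id = character(0), reason = character(0))
  out
}
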
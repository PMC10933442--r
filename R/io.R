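# File formats: EDF signals, CSV hypnogram/events/feature tables, JSON reports.
#
# The EDF writer/reader below covers the plain 16-bit EDF subset the pipeline
# needs (continuous records, 1-second record duration); EDF+ annotation
# streams and vendor extensions are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF field '%s' exceeds %d chars", x, width))
  formatC(x, width = -width)                      # left-justified, space-padded
}

.edf_num <- function(x) {
  # numeric -> <=8 ASCII chars, re-parseable; %.1e always fits
  s <- sprintf("%.6g", x)
  if (nchar(s) > 8) s <- sprintf("%.1e", x)
  s
}

# smallest 8-char-representable value >= x (x > 0); keeps the physical range
# from clipping the signal peaks
.edf_num_ceil <- function(x) {
  s <- .edf_num(x)
  if (as.numeric(s) < x) s <- .edf_num(as.numeric(s) + 10^(floor(log10(x)) - 1))
  s
}

#' Write a recording to an EDF file
#'
#' Plain EDF, 16-bit samples, one-second data records. Each channel is scaled
#' to its own physical range; amplitude resolution is
#' `(phys_max - phys_min) / 65535`. The recording length must be a whole
#' number of seconds (EDF stores complete records only).
#'
#' @param recording A [psg_recording()].
#' @param path Output file path.
#' @param phys_dim Physical dimension string written per channel (default "V";
#'   samples are taken to be volts).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, phys_dim = "V") {
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- n_samples(recording)
  if (n %% fs != 0L) stop("EDF export requires a whole number of seconds of signal")
  n_rec <- n %/% fs
  labels <- names(recording$channels)
  ns <- length(labels)

  pmin_s <- pmax_s <- character(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- recording$channels[[i]]
    amp <- max(abs(x), 1e-9)
    pmax_s[i] <- .edf_num_ceil(amp)
    pmin_s[i] <- paste0("-", pmax_s[i])
    pmin <- as.numeric(pmin_s[i]); pmax <- as.numeric(pmax_s[i])
    d <- round((x - pmin) / (pmax - pmin) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate 01-JAN-2000 X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  for (lab in labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(phys_dim, 8)
  for (i in seq_len(ns)) wr(pmin_s[i], 8)
  for (i in seq_len(ns)) wr(pmax_s[i], 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_rec)) {
    sel <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) writeBin(dig[[i]][sel], con, size = 2L,
                                    endian = "little")
  }
  invisible(path)
}

#' Read selected channels from an EDF file
#'
#' Reads plain 16-bit EDF, returning exactly the requested channels converted
#' to volts (physical dimensions "uV" and "mV" are rescaled; anything else is
#' taken as volts). All requested channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param wanted_channels Character vector of channel labels to return; `NULL`
#'   (default) returns all channels.
#' @return A [psg_recording()].
#' @export
read_recording <- function(path, wanted_channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) stop("not a plain EDF file (version field '", ver, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims  <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr   <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  if (is.null(wanted_channels)) wanted_channels <- labels
  miss <- setdiff(wanted_channels, labels)
  if (length(miss)) {
    stop(sprintf("channel(s) %s not in file; available: %s",
                 paste(miss, collapse = ", "), paste(labels, collapse = ", ")))
  }
  raw <- lapply(seq_len(ns), function(i) integer(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      raw[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
    }
  }
  idx <- match(wanted_channels, labels)
  fs <- unique(spr[idx] / rec_dur)
  if (length(fs) != 1L) stop("requested channels have differing sampling rates")
  unit <- c(uV = 1e-6, mV = 1e-3, V = 1)
  channels <- stats::setNames(lapply(idx, function(i) {
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    u <- if (dims[i] %in% names(unit)) unit[[dims[i]]] else 1
    (pmin[i] + (raw[[i]] - dmin[i]) * scale) * u
  }), wanted_channels)
  psg_recording(channels, fs = fs)
}

#' Write / read a hypnogram CSV (`epoch_index,stage`)
#'
#' @param hyp A [hypnogram()].
#' @param path CSV path.
#' @return `path` invisibly (writer); a [hypnogram()] (reader).
#' @export
write_hypnogram_csv <- function(hyp, path) {
  utils::write.csv(data.frame(epoch_index = seq_along(hyp$labels) - 1L,
                              stage = hyp$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index,stage")
  }
  hypnogram(df$stage[order(df$epoch_index)])
}

#' Write / read an events CSV (`onset_s,duration_s,type`)
#'
#' `type` is `"arousal"` or `"sham"`.
#'
#' @param events An [arousal_events()] table.
#' @param path CSV path.
#' @return `path` invisibly (writer); a raw event data frame (reader — use
#'   [read_annotations()] to also fill the stage at onset).
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(data.frame(onset_s = events$onset,
                              duration_s = events$duration,
                              type = ifelse(events$is_sham, "sham", "arousal")),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read hypnogram and event annotations together
#'
#' Events are validated row by row (negative onset/duration and unknown types
#' are errors naming the offending row), sorted by onset, and annotated with
#' the sleep stage of the epoch containing the onset
#' (epoch index = `floor(onset / 30)`).
#'
#' @param hypnogram_path Hypnogram CSV path.
#' @param events_path Events CSV path.
#' @return A list with elements `hypnogram` and `events`.
#' @export
read_annotations <- function(hypnogram_path, events_path) {
  hyp <- read_hypnogram_csv(hypnogram_path)
  df <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "type")
  if (!all(need %in% names(df))) {
    stop("events CSV must have columns ", paste(need, collapse = ","))
  }
  if (nrow(df) == 0L) {
    return(list(hypnogram = hyp, events = arousal_events()))
  }
  for (i in seq_len(nrow(df))) {
    if (is.na(df$onset_s[i]) || df$onset_s[i] < 0) {
      stop(sprintf("events CSV row %d: negative or missing onset", i))
    }
    if (is.na(df$duration_s[i]) || df$duration_s[i] <= 0) {
      stop(sprintf("events CSV row %d: non-positive or missing duration", i))
    }
    if (!df$type[i] %in% c("arousal", "sham")) {
      stop(sprintf("events CSV row %d: unknown event type '%s'", i, df$type[i]))
    }
  }
  ev <- arousal_events(onset = df$onset_s, duration = df$duration_s,
                       is_sham = df$type == "sham")
  ev$stage <- stage_at(hyp, ev$onset)
  list(hypnogram = hyp, events = ev)
}

#' Write / read a feature table CSV
#'
#' Columns are written in the fixed documented order — `event_id`, `stage`,
#' `level`, then the 136 feature names of [feature_names()] — so tables from
#' different runs are column-compatible.
#'
#' @param matrix A feature matrix data frame from [build_feature_matrix()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the feature data frame (reader).
#' @export
write_feature_table <- function(matrix, path) {
  cols <- c("event_id", "stage", "level", feature_names())
  miss <- setdiff(cols, names(matrix))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "))
  utils::write.csv(matrix[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}

#' Write / read a JSON report
#'
#' Reports round-trip losslessly (full double precision, auto-unboxed
#' scalars).
#'
#' @param report Any JSON-representable list (e.g. a stage report).
#' @param path JSON path.
#' @return `path` invisibly (writer); the parsed list (reader).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
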
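#' Construct an iEEG recording object
#'
#' Container for a multichannel sampled intracranial EEG signal. Samples are
#' stored time-by-channel (one column per channel) in microvolts. Channel
#' labels of the form `<shaft><contact>` (e.g. `A1`, `A2`, `B1`) carry the
#' electrode-shaft grouping used to build the bipolar montage.
#'
#' @param samples numeric matrix, one column per channel (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param channel_labels character vector of channel labels; defaults to the
#'   column names of `samples`.
#' @param events optional ground-truth event ledger (see
#'   [insert_oscillation()]); a data.frame with one row per inserted event.
#' @return An object of class `ieeg_recording`.
#' @export
ieeg_recording <- function(samples, sample_rate, channel_labels = NULL,
                           events = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop_hfoloc("hfoloc_invalid_argument", "samples must be numeric")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop_hfoloc("hfoloc_invalid_argument", "sample_rate must be a positive scalar")
  if (is.null(channel_labels)) channel_labels <- colnames(samples)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_labels) != ncol(samples))
    stop_hfoloc("hfoloc_invalid_argument",
                "channel_labels: expected %d labels, got %d",
                ncol(samples), length(channel_labels))
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sample_rate = sample_rate,
         channel_labels = channel_labels,
         events = events %||% empty_ground_truth()),
    class = "ieeg_recording"
  )
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d channels x %.1f s @ %g Hz\n",
              ncol(x$samples), nrow(x$samples) / x$sample_rate, x$sample_rate))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  if (nrow(x$events) > 0)
    cat(sprintf("  ground-truth events: %d\n", nrow(x$events)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an `ieeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  nrow(recording$samples) / recording$sample_rate
}

# Parse labels like "A1", "B12", "OF3'" into shaft id + contact index.
# Returns data.frame(label, shaft, contact); non-conforming labels get NA.
parse_shaft_labels <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z']+)([0-9]+)$", labels))
  shaft <- vapply(m, function(g) if (length(g) == 3) g[2] else NA_character_, "")
  contact <- vapply(m, function(g) if (length(g) == 3) as.integer(g[3]) else NA_integer_, 1L)
  data.frame(label = labels, shaft = shaft, contact = contact,
             stringsAsFactors = FALSE)
}

#' Read a recording from disk
#'
#' Supports 16-bit EDF and a plain delimited numeric matrix (one column per
#' channel, header row of channel labels). Shaft grouping is inferred from
#' labels of the form `<shaft><contact-number>`.
#'
#' @param path file path.
#' @param format `"edf"` or `"delimited"`.
#' @param sample_rate required for `"delimited"` (the text format does not
#'   carry a rate); ignored for EDF.
#' @param sep field separator for delimited files.
#' @return An [ieeg_recording()].
#' @export
read_recording <- function(path, format = c("delimited", "edf"),
                           sample_rate = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_hfoloc("hfoloc_format_error", "file not found: %s", path)
  if (format == "edf") return(read_edf(path))
  first <- readLines(path, n = 1L)
  labels <- strsplit(first, sep, fixed = TRUE)[[1]]
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, fill = TRUE)
  if (anyNA(raw))
    stop_hfoloc("hfoloc_format_error",
                "channels have unequal length or non-numeric entries (field: samples)")
  if (is.null(sample_rate))
    stop_hfoloc("hfoloc_format_error",
                "missing sample rate for delimited input (field: sample_rate)")
  ieeg_recording(as.matrix(raw), sample_rate, labels)
}

#' Write a recording to disk
#'
#' @param recording an [ieeg_recording()].
#' @param path output path.
#' @param format `"delimited"` (text matrix, header row of labels) or
#'   `"edf"` (16-bit European Data Format, physical dimension microvolts).
#' @param sep field separator for delimited output.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("delimited", "edf"),
                            sep = "\t") {
  format <- match.arg(format)
  if (format == "edf") return(write_edf(recording, path))
  utils::write.table(recording$samples, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

# EDF (16-bit) I/O -----------------------------------------------------------
# Minimal European Data Format writer/reader: 256-byte fixed header,
# 256 bytes per signal, little-endian int16 data records of 1 s each.

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' @rdname write_recording
#' @export
write_edf <- function(recording, path) {
  x <- recording$samples
  fs <- recording$sample_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop_hfoloc("hfoloc_invalid_argument", "EDF export needs an integer sample rate")
  fs <- as.integer(round(fs))
  n <- nrow(x)
  if (n %% fs != 0)
    stop_hfoloc("hfoloc_invalid_argument",
                "EDF export needs a whole number of seconds (1-s data records)")
  n_rec <- n %/% fs
  ns <- ncol(x)
  pmax_ <- apply(abs(x), 2, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, pmax_)
  # physical range as printable 8-char numbers
  pmax_ <- signif(pmax_ * 1.0001, 6)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii("Startdate 01-JAN-2000 X X X", 80),
    "01.01.00", "00.00.00",
    pad_ascii(256 * (1 + ns), 8),
    pad_ascii("", 44),
    pad_ascii(n_rec, 8),
    pad_ascii(1, 8),
    pad_ascii(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  writeChar(paste(vapply(recording$channel_labels, pad_ascii, "", width = 16),
                  collapse = ""), con, eos = NULL)
  writeChar(strrep(pad_ascii("", 80), ns), con, eos = NULL)          # transducer
  writeChar(strrep(pad_ascii("uV", 8), ns), con, eos = NULL)         # phys dim
  writeChar(paste(vapply(-pmax_, pad_ascii, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(pmax_, pad_ascii, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(strrep(pad_ascii(dmin, 8), ns), con, eos = NULL)
  writeChar(strrep(pad_ascii(dmax, 8), ns), con, eos = NULL)
  writeChar(strrep(pad_ascii("", 80), ns), con, eos = NULL)          # prefilter
  writeChar(strrep(pad_ascii(fs, 8), ns), con, eos = NULL)           # samples/record
  writeChar(strrep(pad_ascii("", 32), ns), con, eos = NULL)          # reserved
  scale <- (dmax - dmin) / (2 * pmax_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      d <- as.integer(round((x[idx, j] + pmax_[j]) * scale[j]) + dmin)
      d <- pmin(pmax(d, dmin), dmax)
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_field <- function(con, width, n = 1) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width)), "")
}

#' Read an EDF file
#' @param path EDF file path.
#' @return An [ieeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8 + 80 + 80 + 8 + 8)
  hdr_bytes <- as.integer(read_edf_field(con, 8))
  readChar(con, 44)
  n_rec <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  if (is.na(ns) || ns < 1)
    stop_hfoloc("hfoloc_format_error", "EDF header corrupt (field: number of signals)")
  labels <- read_edf_field(con, 16, ns)
  read_edf_field(con, 80, ns)
  read_edf_field(con, 8, ns)
  pmin_ <- as.numeric(read_edf_field(con, 8, ns))
  pmax_ <- as.numeric(read_edf_field(con, 8, ns))
  dmin <- as.numeric(read_edf_field(con, 8, ns))
  dmax <- as.numeric(read_edf_field(con, 8, ns))
  read_edf_field(con, 80, ns)
  spr <- as.integer(read_edf_field(con, 8, ns))
  read_edf_field(con, 32, ns)
  if (length(unique(spr)) != 1)
    stop_hfoloc("hfoloc_format_error",
                "channels have unequal samples per record (field: nr of samples)")
  if (is.na(rec_dur) || rec_dur <= 0)
    stop_hfoloc("hfoloc_format_error", "EDF header corrupt (field: duration of a data record)")
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[j], size = 2, endian = "little")
      phys <- pmin_[j] + (d - dmin[j]) * (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j])
      out[((r - 1) * spr[j] + 1):(r * spr[j]), j] <- phys
    }
  }
  ieeg_recording(out, fs, labels)
}

# Bipolar montage ------------------------------------------------------------

#' Transform a recording to a bipolar montage
#'
#' For each electrode shaft with k contacts, emits k-1 difference channels
#' `contact_i - contact_(i+1)` labeled `"<shaft>i-<shaft>(i+1)"`. Shafts keep
#' their input order; contacts are paired in ascending order. Shafts with a
#' single contact are skipped with a warning. The low-minus-high sign
#' convention is stated explicitly because it differs across laboratories.
#'
#' @param recording an [ieeg_recording()] with parseable `<shaft><contact>`
#'   labels.
#' @return A bipolar [ieeg_recording()].
#' @export
to_bipolar <- function(recording) {
  info <- parse_shaft_labels(recording$channel_labels)
  if (anyNA(info$shaft))
    stop_hfoloc("hfoloc_format_error",
                "unparseable channel labels: %s (field: channel_labels)",
                paste(info$label[is.na(info$shaft)], collapse = ", "))
  shafts <- unique(info$shaft)
  cols <- list(); labs <- character(0)
  for (s in shafts) {
    rows <- info[info$shaft == s, , drop = FALSE]
    rows <- rows[order(rows$contact), , drop = FALSE]
    if (nrow(rows) < 2) {
      warning(sprintf("shaft %s has a single contact; skipped", s))
      next
    }
    for (i in seq_len(nrow(rows) - 1)) {
      if (rows$contact[i + 1] != rows$contact[i] + 1) next
      a <- rows$label[i]; b <- rows$label[i + 1]
      cols[[length(cols) + 1L]] <-
        recording$samples[, a] - recording$samples[, b]
      labs <- c(labs, paste0(a, "-", b))
    }
  }
  if (length(cols) == 0)
    stop_hfoloc("hfoloc_invalid_argument", "no shaft with >= 2 contacts")
  ieeg_recording(do.call(cbind, cols), recording$sample_rate, labs,
                 events = recording$events)
}

# Slow-wave segment selection ------------------------------------------------

#' Epoch-selection parameters
#'
#' Parameters of the slow-wave-sleep segment rule: a 5-minute run of 30-s
#' epochs in which delta activity (0.5-4 Hz) occupies more than 25% of the
#' background power (0.5-45 Hz).
#'
#' @param epoch_length epoch length in seconds.
#' @param delta_threshold minimum delta power fraction per epoch.
#' @param segment_length required segment length in seconds (multiple of
#'   `epoch_length`).
#' @param delta_band,total_band frequency bands in Hz.
#' @return A list of class `epoch_params`.
#' @export
epoch_params <- function(epoch_length = 30, delta_threshold = 0.25,
                         segment_length = 300, delta_band = c(0.5, 4),
                         total_band = c(0.5, 45)) {
  if (delta_threshold <= 0 || delta_threshold >= 1)
    stop_hfoloc("hfoloc_invalid_argument", "delta_threshold: must be in (0,1)")
  if (abs(segment_length / epoch_length - round(segment_length / epoch_length)) > 1e-9)
    stop_hfoloc("hfoloc_invalid_argument",
                "segment_length: must be an integer multiple of epoch_length")
  structure(list(epoch_length = epoch_length, delta_threshold = delta_threshold,
                 segment_length = segment_length, delta_band = delta_band,
                 total_band = total_band), class = "epoch_params")
}

#' Delta power proportion of an epoch
#'
#' Ratio of averaged-periodogram band power in the delta band to power in the
#' total band. Invariant to amplitude scaling.
#'
#' @param epoch numeric vector, one channel's samples for one epoch.
#' @param sample_rate Hz.
#' @param params an [epoch_params()].
#' @return Fraction in `[0, 1]` (up to spectral leakage).
#' @export
delta_proportion <- function(epoch, sample_rate, params = epoch_params()) {
  min_len <- 2 / params$delta_band[1]
  if (length(epoch) / sample_rate < min_len)
    stop_hfoloc("hfoloc_invalid_argument",
                "epoch shorter than %g s cannot resolve %g Hz", min_len,
                params$delta_band[1])
  psd <- welch_psd(epoch, sample_rate,
                   nperseg = min(length(epoch), round(8 * sample_rate)))
  tot <- band_power(psd, params$total_band)
  if (tot <= 0) return(0)
  band_power(psd, params$delta_band) / tot
}

#' Select the slow-wave analysis segment
#'
#' Scans consecutive 30-s epochs and returns the earliest contiguous run of
#' `segment_length / epoch_length` epochs in which the median-across-channels
#' delta proportion exceeds the threshold in every epoch. Optional exclusion
#' intervals (e.g. 2-h guards around seizures) remove epochs from
#' consideration.
#'
#' @param recording an [ieeg_recording()].
#' @param params an [epoch_params()].
#' @param exclude optional list of `c(start, end)` second intervals to avoid.
#' @return `c(start, end)` in seconds (half-open), with attribute
#'   `epoch_delta_proportions` (median per epoch).
#' @export
select_slow_wave_segment <- function(recording, params = epoch_params(),
                                     exclude = NULL) {
  fs <- recording$sample_rate
  dur <- recording_duration(recording)
  if (dur < params$segment_length)
    stop_hfoloc("hfoloc_invalid_argument",
                "recording (%.0f s) shorter than segment_length (%g s)",
                dur, params$segment_length)
  n_ep <- floor(dur / params$epoch_length)
  need <- as.integer(round(params$segment_length / params$epoch_length))
  med <- numeric(n_ep)
  ok <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    i0 <- (e - 1) * params$epoch_length * fs
    idx <- (i0 + 1):(i0 + params$epoch_length * fs)
    props <- apply(recording$samples[idx, , drop = FALSE], 2,
                   delta_proportion, sample_rate = fs, params = params)
    med[e] <- stats::median(props)
    ok[e] <- med[e] > params$delta_threshold
    if (!is.null(exclude)) {
      t0 <- (e - 1) * params$epoch_length; t1 <- e * params$epoch_length
      for (iv in exclude)
        if (t0 < iv[2] && t1 > iv[1]) ok[e] <- FALSE
    }
  }
  run <- 0L
  for (e in seq_len(n_ep)) {
    run <- if (ok[e]) run + 1L else 0L
    if (run == need) {
      start <- (e - need) * params$epoch_length
      out <- c(start = start, end = start + params$segment_length)
      attr(out, "epoch_delta_proportions") <- med
      return(out)
    }
  }
  stop_hfoloc("hfoloc_no_slow_wave_segment",
              "no run of %d consecutive epochs with delta proportion > %g",
              need, params$delta_threshold)
}

#' Extract a time window from a recording
#' @param recording an [ieeg_recording()].
#' @param interval `c(start, end)` seconds, half-open.
#' @return The cropped [ieeg_recording()] (ground-truth event times shifted).
#' @export
crop_recording <- function(recording, interval) {
  fs <- recording$sample_rate
  i0 <- round(interval[1] * fs)
  i1 <- round(interval[2] * fs)
  ev <- recording$events
  if (nrow(ev) > 0) {
    keep <- ev$onset >= interval[1] & (ev$onset + ev$duration) <= interval[2]
    ev <- ev[keep, , drop = FALSE]
    ev$onset <- ev$onset - interval[1]
  }
  ieeg_recording(recording$samples[(i0 + 1):i1, , drop = FALSE], fs,
                 recording$channel_labels, events = ev)
}
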
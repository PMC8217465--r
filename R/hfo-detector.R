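#' Detection parameters
#'
#' Thresholds and bands of the automated ripple / fast-ripple detector.
#' Defaults follow the published protocol: ripple band 80-200 Hz, fast-ripple
#' band 200-500 Hz; an event needs at least eight consecutive peaks above
#' 3 SD over the baseline mean peak amplitude, containing at least six
#' consecutive peaks above 10 SD (ripples) or 9.5 SD (fast ripples);
#' baselines come from the PPDC turning point within 5-s windows.
#'
#' @param ripple_band,fr_band band edges in Hz; must be ordered and
#'   non-overlapping.
#' @param long_run_peaks,long_run_sd length and SD multiplier of the low
#'   ("long") run condition.
#' @param short_run_peaks length of the high ("short") run condition, which
#'   must nest inside the long run.
#' @param ripple_short_run_sd,fr_short_run_sd band-specific SD multipliers
#'   for the short run.
#' @param baseline_window PPDC baseline window in seconds.
#' @param baseline_hop hop between baseline windows in seconds; the default
#'   equals `baseline_window` (contiguous non-overlapping windows with
#'   thresholds constant within a window); set e.g. 1 for a sliding window.
#' @param merge_gap events closer than this many seconds are merged.
#' @param gibbs_offset_fraction offset of the comparison frequency in the
#'   Gibbs discriminator, as a fraction of the band width.
#' @param gibbs_min_offset_hz floor for the comparison frequency (Hz).
#' @param gibbs_margin raw-segment margin around an event in seconds.
#' @param gibbs_smooth_hz half-width of the spectral smoothing neighborhood.
#' @param filter_order FIR order of the zero-phase bandpass.
#' @param min_peaks_per_window minimum peaks for a windowed PPDC; windows
#'   with fewer fall back to the whole-channel PPDC.
#' @param sd_floor_frac degenerate baseline SD (= 0) is replaced by this
#'   fraction of the baseline mean.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(ripple_band = c(80, 200), fr_band = c(200, 500),
                             long_run_peaks = 8, long_run_sd = 3,
                             short_run_peaks = 6, ripple_short_run_sd = 10,
                             fr_short_run_sd = 9.5, baseline_window = 5,
                             baseline_hop = NULL, merge_gap = 0.010,
                             gibbs_offset_fraction = 0.5,
                             gibbs_min_offset_hz = 30, gibbs_margin = 0.05,
                             gibbs_smooth_hz = 10, filter_order = 600,
                             min_peaks_per_window = 20, sd_floor_frac = 0.05) {
  chk_band <- function(b, nm) {
    if (length(b) != 2 || b[1] >= b[2])
      stop_hfoloc("hfoloc_invalid_argument", "%s: edges must be increasing", nm)
  }
  chk_band(ripple_band, "ripple_band")
  chk_band(fr_band, "fr_band")
  if (ripple_band[2] > fr_band[1])
    stop_hfoloc("hfoloc_invalid_argument",
                "ripple_band/fr_band: bands must be ordered and non-overlapping")
  if (short_run_peaks > long_run_peaks)
    stop_hfoloc("hfoloc_invalid_argument",
                "short_run_peaks: must be <= long_run_peaks")
  if (any(c(long_run_sd, ripple_short_run_sd, fr_short_run_sd) <= 0))
    stop_hfoloc("hfoloc_invalid_argument", "SD multipliers must be > 0")
  structure(list(ripple_band = ripple_band, fr_band = fr_band,
                 long_run_peaks = as.integer(long_run_peaks),
                 long_run_sd = long_run_sd,
                 short_run_peaks = as.integer(short_run_peaks),
                 ripple_short_run_sd = ripple_short_run_sd,
                 fr_short_run_sd = fr_short_run_sd,
                 baseline_window = baseline_window,
                 baseline_hop = baseline_hop %||% baseline_window,
                 merge_gap = merge_gap,
                 gibbs_offset_fraction = gibbs_offset_fraction,
                 gibbs_min_offset_hz = gibbs_min_offset_hz,
                 gibbs_margin = gibbs_margin,
                 gibbs_smooth_hz = gibbs_smooth_hz,
                 filter_order = as.integer(filter_order),
                 min_peaks_per_window = as.integer(min_peaks_per_window),
                 sd_floor_frac = sd_floor_frac),
            class = "detection_params")
}

band_for <- function(params, band_label) {
  switch(band_label, ripple = params$ripple_band,
         `fast-ripple` = params$fr_band,
         stop_hfoloc("hfoloc_invalid_argument", "unknown band %s", band_label))
}

#' Zero-phase FIR bandpass filter
#'
#' Applies a linear-phase FIR bandpass (Hamming-window design) with zero net
#' phase shift. The forward-backward pass is computed in the frequency
#' domain: the signal, reflection-padded by one filter length at each end,
#' is multiplied by the squared magnitude response |H(w)|^2, which is
#' algebraically identical to filtering twice with time reversal and keeps
#' the cost at O(n log n) for long recordings.
#'
#' @param x numeric signal.
#' @param sample_rate Hz.
#' @param band `c(low, high)` in Hz, inside `(0, sample_rate/2)`.
#' @param order FIR order.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, sample_rate, band, order = 600) {
  if (band[1] <= 0 || band[2] >= sample_rate / 2)
    stop_hfoloc("hfoloc_invalid_argument",
                "band: edges must lie inside (0, Nyquist = %g Hz)", sample_rate / 2)
  h <- signal::fir1(order, band / (sample_rate / 2), type = "pass")
  n <- length(x)
  pad <- min(order, n - 1L)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  N <- stats::nextn(length(xe) + length(h), c(2, 3, 5))
  Hf <- stats::fft(c(h, rep(0, N - length(h))))
  Xf <- stats::fft(c(xe, rep(0, N - length(xe))))
  y <- Re(stats::fft(Xf * Mod(Hf)^2, inverse = TRUE)) / N
  # |H|^2 is H times its conjugate: the net impulse response is symmetric
  # about zero, so no group-delay compensation is needed
  y[(pad + 1):(pad + n)]
}

#' Extract amplitude peaks of a filtered signal
#'
#' Indices and absolute amplitudes of the strict local maxima of
#' `|filtered|`; plateaus take their first index. Each half-cycle of an
#' oscillation yields one absolute peak, so eight consecutive peaks
#' correspond to about four cycles.
#'
#' @param filtered filtered signal.
#' @return A list of class `peak_series` with `times` (sample indices,
#'   strictly increasing) and `amplitudes` (>= 0).
#' @export
extract_peaks <- function(filtered) {
  a <- abs(filtered)
  n <- length(a)
  if (n < 3) return(structure(list(times = integer(0), amplitudes = numeric(0)),
                              class = "peak_series"))
  idx <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1L
  structure(list(times = idx, amplitudes = a[idx]), class = "peak_series")
}

# Turning point of the ascending sorted amplitude curve (PPDC): the index of
# maximum perpendicular distance below the chord joining the endpoints, with
# both axes normalized to [0,1]. A flat chord (all amplitudes equal) is
# degenerate: the turning point is the last index.
ppdc_turning_point <- function(sorted_amps) {
  n <- length(sorted_amps)
  if (n < 3 || sorted_amps[n] == sorted_amps[1]) return(n)
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (sorted_amps - sorted_amps[1]) / (sorted_amps[n] - sorted_amps[1])
  which.max(xs - ys)
}

ppdc_stats <- function(amps, sd_floor_frac) {
  a <- sort(amps)
  k <- ppdc_turning_point(a)
  base <- if (k > 1) a[seq_len(k - 1)] else a[1]
  m <- mean(base)
  s <- if (length(base) > 1) stats::sd(base) else 0
  if (s == 0) s <- sd_floor_frac * m
  list(mean = m, sd = s, turning_index = k)
}

#' PPDC baseline estimate per 5-s window
#'
#' Within each baseline window the absolute peak amplitudes are ranked in
#' ascending order (the peak point distribution curve); all peaks strictly
#' before its turning point are baseline points, and their mean and SD define
#' the detection thresholds for that window. Windows with too few peaks fall
#' back to the whole-channel PPDC (recorded in the `fallback` column).
#'
#' @param peaks a [extract_peaks()] `peak_series`.
#' @param n_samples length of the filtered signal in samples.
#' @param sample_rate Hz.
#' @param params a [detection_params()].
#' @return A data.frame of class `baseline_estimate`, one row per window:
#'   `window`, `start_s`, `end_s`, `mean`, `sd`, `turning_index`, `n_peaks`,
#'   `fallback`.
#' @export
ppdc_baseline <- function(peaks, n_samples, sample_rate,
                          params = detection_params()) {
  if (length(peaks$times) == 0)
    stop_hfoloc("hfoloc_degenerate_baseline", "channel has no amplitude peaks")
  w <- params$baseline_window
  hop <- params$baseline_hop
  dur <- n_samples / sample_rate
  starts <- seq(0, max(0, dur - 1e-9), by = hop)
  starts <- starts[starts < dur]
  global <- ppdc_stats(peaks$amplitudes, params$sd_floor_frac)
  t_s <- peaks$times / sample_rate
  rows <- lapply(seq_along(starts), function(i) {
    s0 <- starts[i]
    s1 <- if (i == length(starts)) dur else min(s0 + w, dur)
    sel <- t_s >= s0 & t_s < s1
    if (sum(sel) >= params$min_peaks_per_window) {
      st <- ppdc_stats(peaks$amplitudes[sel], params$sd_floor_frac)
      fb <- FALSE
    } else {
      st <- global
      fb <- TRUE
    }
    data.frame(window = i, start_s = s0, end_s = s1, mean = st$mean,
               sd = st$sd, turning_index = st$turning_index,
               n_peaks = sum(sel), fallback = fb)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("baseline_estimate", class(out))
  out
}

# Window index (row of baselines) containing time t seconds; events are
# assigned to the window of their first peak.
window_of <- function(baselines, t) {
  i <- findInterval(t, baselines$start_s)
  min(max(i, 1L), nrow(baselines))
}

max_consecutive <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Detect candidate HFO events from thresholded peak runs
#'
#' A candidate is a maximal run of at least `long_run_peaks` consecutive
#' peaks above `mean + long_run_sd * sd`, containing at least
#' `short_run_peaks` consecutive peaks above the band's high threshold
#' (10 SD for ripples, 9.5 SD for fast ripples). Thresholds come from the
#' baseline window containing the run's first peak. Candidates separated by
#' less than `merge_gap` are merged. The retained flag is left unset
#' (`NA`) - Gibbs screening happens downstream.
#'
#' @param peaks a `peak_series` from the band-filtered signal.
#' @param baselines a [ppdc_baseline()] estimate.
#' @param band `"ripple"` or `"fast-ripple"`.
#' @param sample_rate Hz.
#' @param params a [detection_params()].
#' @param channel channel label recorded in the output.
#' @return Event data.frame: `channel`, `band`, `start_s`, `end_s`,
#'   `n_peaks_long`, `n_peaks_short`, `peak_amplitude`, `gibbs_delta`,
#'   `retained`.
#' @export
detect_candidates <- function(peaks, baselines, band = c("ripple", "fast-ripple"),
                              sample_rate, params = detection_params(),
                              channel = "ch") {
  band <- match.arg(band)
  hi_mult <- if (band == "ripple") params$ripple_short_run_sd else params$fr_short_run_sd
  empty <- empty_event_table()
  np <- length(peaks$times)
  if (np == 0) return(empty)
  t_s <- peaks$times / sample_rate
  wi <- vapply(t_s, window_of, 1L, baselines = baselines)
  low_thr <- baselines$mean[wi] + params$long_run_sd * baselines$sd[wi]
  q_low <- peaks$amplitudes > low_thr
  r <- rle(q_low)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  events <- list()
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] < params$long_run_peaks) next
    i0 <- begins[k]; i1 <- ends[k]
    w <- wi[i0]                                  # window of first peak
    hi_thr <- baselines$mean[w] + hi_mult * baselines$sd[w]
    seg <- peaks$amplitudes[i0:i1]
    n_short <- max_consecutive(seg > hi_thr)
    if (n_short < params$short_run_peaks) next
    events[[length(events) + 1L]] <- data.frame(
      channel = channel, band = band,
      start_s = t_s[i0], end_s = t_s[i1],
      n_peaks_long = i1 - i0 + 1L, n_peaks_short = as.integer(n_short),
      peak_amplitude = max(seg), gibbs_delta = NA_real_, retained = NA,
      stringsAsFactors = FALSE)
  }
  if (length(events) == 0) return(empty)
  ev <- do.call(rbind, events)
  merge_events(ev, params$merge_gap)
}

empty_event_table <- function() {
  data.frame(channel = character(0), band = character(0), start_s = numeric(0),
             end_s = numeric(0), n_peaks_long = integer(0),
             n_peaks_short = integer(0), peak_amplitude = numeric(0),
             gibbs_delta = numeric(0), retained = logical(0),
             stringsAsFactors = FALSE)
}

merge_events <- function(ev, merge_gap) {
  if (nrow(ev) < 2) return(ev)
  ev <- ev[order(ev$start_s), , drop = FALSE]
  keep <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    j <- nrow(keep)
    if (ev$start_s[i] - keep$end_s[j] < merge_gap) {
      keep$end_s[j] <- max(keep$end_s[j], ev$end_s[i])
      keep$n_peaks_long[j] <- keep$n_peaks_long[j] + ev$n_peaks_long[i]
      keep$n_peaks_short[j] <- max(keep$n_peaks_short[j], ev$n_peaks_short[i])
      keep$peak_amplitude[j] <- max(keep$peak_amplitude[j], ev$peak_amplitude[i])
    } else {
      keep <- rbind(keep, ev[i, , drop = FALSE])
    }
  }
  rownames(keep) <- NULL
  keep
}

#' Gibbs-effect discriminator: frequency-offset power difference
#'
#' Distinguishes genuine band-limited oscillations from the ringing a
#' zero-phase bandpass produces on sharp transients. The raw (unfiltered)
#' segment around the event, including margins, is examined with a
#' Hann-windowed periodogram zero-padded to a 1-Hz grid and smoothed over
#' +/-`gibbs_smooth_hz`. With `f*` the in-band power maximum, the statistic
#' is `delta = P(f*) - P(f_off)` where
#' `f_off = max(f* - gibbs_offset_fraction * bandwidth, gibbs_min_offset_hz)`.
#' A genuine oscillation has a local spectral peak, so `delta > 0`; spike
#' ringing rides a monotone-decreasing spectrum, so `delta <= 0` and the
#' event is rejected.
#'
#' @param raw_segment raw signal samples covering the event plus margins of
#'   at least `gibbs_margin` seconds.
#' @param sample_rate Hz.
#' @param band `c(low, high)` Hz of the detection band.
#' @param params a [detection_params()].
#' @return A list with `delta` (power difference), `f_star`, `f_offset` and
#'   `keep` (`delta > 0`).
#' @export
gibbs_power_difference <- function(raw_segment, sample_rate, band,
                                   params = detection_params()) {
  n <- length(raw_segment)
  if (n < sample_rate / 10)
    stop_hfoloc("hfoloc_invalid_argument",
                "segment too short (%d samples) for 10 Hz spectral resolution", n)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  npad <- stats::nextn(max(n, round(sample_rate)), 2)
  S <- Mod(stats::fft(c(raw_segment * w, rep(0, npad - n))))^2
  half <- seq_len(npad %/% 2)
  f <- (half - 1) * sample_rate / npad
  S <- S[half]
  sm <- function(f0) mean(S[f >= f0 - params$gibbs_smooth_hz &
                            f <= f0 + params$gibbs_smooth_hz])
  grid <- seq(band[1], band[2], by = 1)
  Pb <- vapply(grid, sm, 0)
  f_star <- grid[which.max(Pb)]
  f_off <- max(f_star - params$gibbs_offset_fraction * (band[2] - band[1]),
               params$gibbs_min_offset_hz)
  delta <- sm(f_star) - sm(f_off)
  list(delta = delta, f_star = f_star, f_offset = f_off, keep = delta > 0)
}

#' Run the full HFO detection pipeline on a recording
#'
#' Per channel and band: zero-phase bandpass, peak extraction, PPDC baseline,
#' consecutive-peak candidate detection, then Gibbs screening of each
#' candidate against the raw signal. The input is expected to be bipolar and
#' segment-selected already. Channels with a degenerate baseline (no peaks)
#' are skipped with a warning.
#'
#' @param recording an [ieeg_recording()].
#' @param params a [detection_params()].
#' @return Event table (see [detect_candidates()]) with `retained` and
#'   `gibbs_delta` filled in; attributes `analyzed_duration_s`, `channels`
#'   and `skipped_channels`.
#' @export
detect_hfos <- function(recording, params = detection_params()) {
  fs <- recording$sample_rate
  n <- nrow(recording$samples)
  all_events <- list()
  skipped <- character(0)
  for (ch in recording$channel_labels) {
    x <- recording$samples[, ch]
    for (band_label in c("ripple", "fast-ripple")) {
      band <- band_for(params, band_label)
      filt <- bandpass_zero_phase(x, fs, band, params$filter_order)
      pk <- extract_peaks(filt)
      bl <- tryCatch(ppdc_baseline(pk, n, fs, params),
                     hfoloc_degenerate_baseline = function(e) NULL)
      if (is.null(bl)) {
        skipped <- unique(c(skipped, ch))
        warning(sprintf("channel %s: degenerate baseline, skipped", ch))
        next
      }
      ev <- detect_candidates(pk, bl, band_label, fs, params, channel = ch)
      if (nrow(ev) > 0) {
        for (i in seq_len(nrow(ev))) {
          i0 <- max(1L, round((ev$start_s[i] - params$gibbs_margin) * fs))
          i1 <- min(n, round((ev$end_s[i] + params$gibbs_margin) * fs))
          i1 <- max(i1, i0 + ceiling(fs / 10))   # ensure spectral resolution
          i1 <- min(i1, n)
          i0 <- min(i0, max(1L, i1 - ceiling(fs / 10)))
          g <- gibbs_power_difference(x[i0:i1], fs, band, params)
          ev$gibbs_delta[i] <- g$delta
          ev$retained[i] <- g$keep
        }
        all_events[[length(all_events) + 1L]] <- ev
      }
    }
  }
  out <- if (length(all_events)) do.call(rbind, all_events) else empty_event_table()
  rownames(out) <- NULL
  attr(out, "analyzed_duration_s") <- n / fs
  attr(out, "channels") <- recording$channel_labels
  attr(out, "skipped_channels") <- skipped
  out
}

#' Per-channel, per-band HFO rates
#'
#' @param events an event table from [detect_hfos()].
#' @param duration_s analyzed duration in seconds (> 0); defaults to the
#'   table's `analyzed_duration_s` attribute.
#' @param channels channel labels to report (zero-rate channels included);
#'   defaults to the table's `channels` attribute.
#' @return data.frame `channel`, `band`, `n_events`, `rate_per_min`
#'   (retained events only).
#' @export
channel_rates <- function(events, duration_s = NULL, channels = NULL) {
  duration_s <- duration_s %||% attr(events, "analyzed_duration_s")
  channels <- channels %||% attr(events, "channels") %||% unique(events$channel)
  if (is.null(duration_s) || duration_s <= 0)
    stop_hfoloc("hfoloc_invalid_argument", "duration_s: must be > 0")
  kept <- events[!is.na(events$retained) & events$retained, , drop = FALSE]
  grid <- expand.grid(channel = channels, band = c("ripple", "fast-ripple"),
                      stringsAsFactors = FALSE)
  grid$n_events <- mapply(function(ch, b)
    sum(kept$channel == ch & kept$band == b), grid$channel, grid$band)
  grid$rate_per_min <- grid$n_events / (duration_s / 60)
  grid
}

#' Write an event table as TSV
#' @param events event table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
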
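# Shared fixture builders. All randomness is seeded by the caller.

# Short background recording with simple labels.
make_background <- function(n_channels = 1, duration = 20, seed = 1,
                            noise_sigma = 20, sample_rate = 4096,
                            labels = NULL) {
  generate_background(sim_config(
    n_channels = n_channels, duration = duration, sample_rate = sample_rate,
    noise_sigma = noise_sigma, seed = seed,
    channel_labels = labels %||% paste0("A", seq_len(n_channels))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recording built from explicit per-channel signals (matrix columns).
make_recording <- function(..., sample_rate = 4096, labels = NULL) {
  m <- cbind(...)
  ieeg_recording(m, sample_rate,
                 labels %||% paste0("A", seq_len(ncol(m))))
}

burst_event <- function(channel = "A1", onset = 5, frequency = 150,
                        n_cycles = 12, amplitude = 12) {
  kind <- if (frequency < 200) "ripple-burst" else "fr-burst"
  ground_truth_event(channel, kind, onset = onset, amplitude = amplitude,
                     frequency = frequency, n_cycles = n_cycles)
}

spike_event <- function(channel = "A1", onset = 5, amplitude = 15,
                        width = 0.02) {
  ground_truth_event(channel, "spike-transient", onset = onset,
                     amplitude = amplitude, duration = width)
}

# Fraction of [a0,a1) overlapped by [b0,b1).
overlap_frac <- function(a0, a1, b0, b1) {
  max(0, min(a1, b1) - max(a0, b0)) / (a1 - a0)
}

# Match retained events against a ground-truth ledger.
# Returns list(recall, precision, n_truth, n_detected).
score_detection <- function(events, truth) {
  band_of <- function(kind) ifelse(kind == "ripple-burst", "ripple", "fast-ripple")
  kept <- events[!is.na(events$retained) & events$retained, , drop = FALSE]
  bursts <- truth[truth$is_hfo, , drop = FALSE]
  hit <- vapply(seq_len(nrow(bursts)), function(i) {
    b <- bursts[i, ]
    cand <- kept[kept$channel == b$channel & kept$band == band_of(b$kind), , drop = FALSE]
    nrow(cand) > 0 &&
      any(pmin(cand$end_s, b$onset + b$duration) - pmax(cand$start_s, b$onset) > 0)
  }, TRUE)
  tp <- vapply(seq_len(nrow(kept)), function(i) {
    e <- kept[i, ]
    b <- bursts[bursts$channel == e$channel & band_of(bursts$kind) == e$band, , drop = FALSE]
    nrow(b) > 0 &&
      any(pmin(e$end_s, b$onset + b$duration) - pmax(e$start_s, b$onset) > 0)
  }, TRUE)
  list(recall = mean(hit), precision = if (nrow(kept)) mean(tp) else NA_real_,
       n_truth = nrow(bursts), n_detected = nrow(kept))
}

# Brute-force candidate scan used as the oracle for detect_candidates():
# checks every contiguous peak run against the two threshold conditions.
brute_force_candidates <- function(peaks, baselines, band, sample_rate, params) {
  hi_mult <- if (band == "ripple") params$ripple_short_run_sd else params$fr_short_run_sd
  np <- length(peaks$times)
  t_s <- peaks$times / sample_rate
  win_of <- function(t) {
    i <- findInterval(t, baselines$start_s)
    min(max(i, 1L), nrow(baselines))
  }
  qualifies_low <- function(i) {
    w <- win_of(t_s[i])
    peaks$amplitudes[i] > baselines$mean[w] + params$long_run_sd * baselines$sd[w]
  }
  q <- vapply(seq_len(np), qualifies_low, TRUE)
  out <- list()
  i <- 1
  while (i <= np) {
    if (!q[i]) { i <- i + 1; next }
    j <- i
    while (j < np && q[j + 1]) j <- j + 1
    if (j - i + 1 >= params$long_run_peaks) {
      w <- win_of(t_s[i])
      hi <- baselines$mean[w] + hi_mult * baselines$sd[w]
      run <- peaks$amplitudes[i:j] > hi
      best <- 0; cur <- 0
      for (v in run) { cur <- if (v) cur + 1 else 0; best <- max(best, cur) }
      if (best >= params$short_run_peaks)
        out[[length(out) + 1]] <- c(start = t_s[i], end = t_s[j])
    }
    i <- j + 1
  }
  out
}
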
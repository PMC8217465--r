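#' Simulation configuration
#'
#' Settings for the synthetic iEEG background generator: Gaussian 1/f^alpha
#' noise produced by spectral shaping of white noise, independently per
#' channel, normalized to a target standard deviation. One integer master
#' seed fixes all randomness; per-channel sub-streams are derived by counter.
#'
#' @param n_channels number of channels (>= 1).
#' @param duration recording length in seconds (> 0).
#' @param sample_rate sampling rate in Hz (> 1000, so 500 Hz is resolvable).
#' @param noise_sigma target per-channel standard deviation (microvolts).
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param seed integer master seed.
#' @param channel_labels optional labels; default `<shaft><contact>` style
#'   labels `A1..A<k>`, `B1..` with 8 contacts per shaft.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 10, duration = 300, sample_rate = 4096,
                       noise_sigma = 20, noise_exponent = 1, seed = 1,
                       channel_labels = NULL) {
  if (n_channels < 1) stop_hfoloc("hfoloc_invalid_argument", "n_channels: must be >= 1")
  if (duration <= 0) stop_hfoloc("hfoloc_invalid_argument", "duration: must be > 0")
  if (sample_rate <= 1000)
    stop_hfoloc("hfoloc_invalid_argument",
                "sample_rate: must exceed 1000 Hz to resolve 500 Hz")
  if (is.null(channel_labels)) {
    shaft <- LETTERS[ceiling(seq_len(n_channels) / 8)]
    contact <- ((seq_len(n_channels) - 1) %% 8) + 1
    channel_labels <- paste0(shaft, contact)
  }
  structure(list(n_channels = as.integer(n_channels), duration = duration,
                 sample_rate = sample_rate, noise_sigma = noise_sigma,
                 noise_exponent = noise_exponent, seed = as.integer(seed),
                 channel_labels = channel_labels),
            class = "sim_config")
}

empty_ground_truth <- function() {
  data.frame(channel = character(0), kind = character(0), onset = numeric(0),
              duration = numeric(0), frequency = numeric(0),
              amplitude = numeric(0), n_cycles = integer(0),
              is_hfo = logical(0), stringsAsFactors = FALSE)
}

# Per-channel sub-stream: deterministic function of (master seed, counter).
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 104729) %% 2147483647)
}

# 1/f^alpha noise of length n, exact sample SD = sigma.
shaped_noise <- function(n, alpha, sigma) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- c(1, seq_len(n - 1))
  fr <- pmin(k, n - k)            # symmetric frequency index
  H <- fr^(-alpha / 2)
  H[1] <- 0                       # zero-mean: drop DC
  x <- Re(stats::fft(W * H, inverse = TRUE)) / n
  x * sigma / stats::sd(x)
}

#' Generate a 1/f background recording
#'
#' @param config a [sim_config()].
#' @return An [ieeg_recording()] with an empty ground-truth ledger.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$duration * config$sample_rate)
  out <- matrix(0, nrow = n, ncol = config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    set.seed(derive_seed(config$seed, ch))
    out[, ch] <- shaped_noise(n, config$noise_exponent, config$noise_sigma)
  }
  ieeg_recording(out, config$sample_rate, config$channel_labels)
}

#' Ground-truth event description
#'
#' @param channel channel label.
#' @param kind `"ripple-burst"`, `"fr-burst"` or `"spike-transient"`.
#' @param onset onset in seconds from recording start.
#' @param amplitude peak amplitude in multiples of the local background SD.
#'   For bursts this is the SD of the band-filtered background (the burst's
#'   own band) in a 1-s neighborhood, so the detector's relative SD
#'   thresholds map onto ground-truth amplitude; for broadband spike
#'   transients it is the raw local SD.
#' @param frequency burst frequency in Hz (bursts only).
#' @param n_cycles number of oscillation cycles (bursts only; >= 4 for a
#'   detectable HFO).
#' @param duration event duration in seconds; for bursts computed as
#'   `n_cycles / frequency`, for spikes the transient width (<= 80 ms).
#' @return A one-row data.frame matching the ground-truth ledger schema.
#' @export
ground_truth_event <- function(channel, kind = c("ripple-burst", "fr-burst",
                                                 "spike-transient"),
                               onset, amplitude, frequency = NA_real_,
                               n_cycles = NA_integer_, duration = NULL) {
  kind <- match.arg(kind)
  if (onset < 0) stop_hfoloc("hfoloc_invalid_argument", "onset: must be >= 0")
  if (kind != "spike-transient") {
    if (is.na(frequency))
      stop_hfoloc("hfoloc_invalid_argument", "frequency: required for bursts")
    band <- if (kind == "ripple-burst") c(80, 200) else c(200, 500)
    if (frequency < band[1] || frequency > band[2])
      stop_hfoloc("hfoloc_invalid_argument",
                  "frequency: %g Hz outside the %s band (%g-%g Hz)",
                  frequency, sub("-burst", "", kind), band[1], band[2])
    if (is.na(n_cycles)) stop_hfoloc("hfoloc_invalid_argument", "n_cycles: required for bursts")
    duration <- n_cycles / frequency
  } else {
    if (is.null(duration))
      stop_hfoloc("hfoloc_invalid_argument", "duration: required for spike transients")
    if (duration > 0.080)
      stop_hfoloc("hfoloc_invalid_argument", "duration: spike width must be <= 80 ms")
  }
  data.frame(channel = channel, kind = kind, onset = onset,
             duration = duration, frequency = frequency,
             amplitude = amplitude,
             n_cycles = as.integer(n_cycles),
             is_hfo = kind != "spike-transient",
             stringsAsFactors = FALSE)
}

local_background_sd <- function(x, idx, fs) {
  lo <- max(1L, idx[1] - fs %/% 2L)
  hi <- min(length(x), idx[length(idx)] + fs %/% 2L)
  stats::sd(x[lo:hi])
}

# SD of the band-filtered local background around the insertion site.
# The neighborhood is filtered with margins so filter edge effects stay
# outside the part whose SD is measured.
local_band_sd <- function(x, idx, fs, band) {
  margin <- fs %/% 2L
  lo <- max(1L, idx[1] - 2L * margin)
  hi <- min(length(x), idx[length(idx)] + 2L * margin)
  seg <- bandpass_zero_phase(x[lo:hi], fs, band)
  core <- seg[max(1, margin):(length(seg) - max(1, min(margin, length(seg) - 1)))]
  stats::sd(core)
}

#' Insert an oscillatory burst into a recording
#'
#' Adds a Hann-tapered sinusoid of the stated frequency, cycle count and
#' amplitude to one channel. Amplitude is expressed in multiples of the
#' band-filtered local background SD (ripple or fast-ripple band per the
#' event kind): detection thresholds are relative to the in-band baseline,
#' so this is the scale on which "x SD" ground truth is meaningful. All
#' other samples are unchanged and the event is appended to the
#' ground-truth ledger.
#'
#' @param recording an [ieeg_recording()].
#' @param event a burst-kind [ground_truth_event()].
#' @return The modified recording.
#' @export
insert_oscillation <- function(recording, event) {
  if (!event$kind %in% c("ripple-burst", "fr-burst"))
    stop_hfoloc("hfoloc_invalid_argument", "event kind must be a burst")
  fs <- recording$sample_rate
  if (event$frequency <= 0 || event$frequency >= fs / 2)
    stop_hfoloc("hfoloc_invalid_argument",
                "frequency: %g Hz outside (0, fs/2)", event$frequency)
  if (event$onset + event$duration > recording_duration(recording) + 1e-9)
    stop_hfoloc("hfoloc_invalid_argument", "event does not fit inside the recording")
  n <- round(event$duration * fs)
  idx <- round(event$onset * fs) + seq_len(n)
  ch <- match(event$channel, recording$channel_labels)
  if (is.na(ch)) stop_hfoloc("hfoloc_invalid_argument",
                             "channel %s not in recording", event$channel)
  x <- recording$samples[, ch]
  band <- if (event$kind == "ripple-burst") c(80, 200) else c(200, 500)
  loc_sd <- local_band_sd(x, idx, as.integer(fs), band)
  tt <- (seq_len(n) - 1) / fs
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  burst <- event$amplitude * loc_sd * sin(2 * pi * event$frequency * tt) * hann
  recording$samples[idx, ch] <- x[idx] + burst
  recording$events <- rbind(recording$events, event)
  recording
}

#' Insert a sharp non-oscillatory transient (spike)
#'
#' Adds a Gaussian-envelope monophasic deflection (no oscillation) whose
#' envelope SD is `duration / 8`, so the support is about the stated width.
#' Sharp enough that its filter ringing crosses the detector's amplitude
#' thresholds - this is the false-HFO generator the Gibbs discriminator must
#' reject. Ground truth records it as a non-HFO.
#'
#' @param recording an [ieeg_recording()].
#' @param event a spike-transient [ground_truth_event()].
#' @return The modified recording.
#' @export
insert_transient <- function(recording, event) {
  if (event$kind != "spike-transient")
    stop_hfoloc("hfoloc_invalid_argument", "event kind must be spike-transient")
  fs <- recording$sample_rate
  if (event$onset + event$duration > recording_duration(recording) + 1e-9)
    stop_hfoloc("hfoloc_invalid_argument", "event does not fit inside the recording")
  n <- round(event$duration * fs)
  idx <- round(event$onset * fs) + seq_len(n)
  ch <- match(event$channel, recording$channel_labels)
  if (is.na(ch)) stop_hfoloc("hfoloc_invalid_argument",
                             "channel %s not in recording", event$channel)
  x <- recording$samples[, ch]
  loc_sd <- local_background_sd(x, idx, as.integer(fs))
  tt <- (seq_len(n) - (n + 1) / 2) / fs
  pulse <- event$amplitude * loc_sd * exp(-0.5 * (tt / (event$duration / 8))^2)
  recording$samples[idx, ch] <- x[idx] + pulse
  recording$events <- rbind(recording$events, event)
  recording
}

#' Write the ground-truth ledger to JSON
#' @param recording an [ieeg_recording()] carrying ground-truth events.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(recording, path) {
  jsonlite::write_json(recording$events, path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}

# Synthetic cohorts ----------------------------------------------------------

#' Synthetic cohort specification
#'
#' @param n_patients number of patients.
#' @param p_seizure_free probability of Engel class I outcome.
#' @param region_vocabulary region labels to draw marked/removed sets from.
#' @param p_complete_removal_given_good,p_complete_removal_given_poor
#'   probability that the HFO-marked set is completely removed, conditional
#'   on outcome; these two probabilities induce the removal-outcome
#'   association the contingency analyses measure.
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 15, p_seizure_free = 0.33,
                        region_vocabulary = c("LF", "LT", "LP", "LO", "LH",
                                              "RF", "RT", "RP", "RO", "RH"),
                        p_complete_removal_given_good = 0.9,
                        p_complete_removal_given_poor = 0.2,
                        seed = 1) {
  probs <- c(p_seizure_free, p_complete_removal_given_good,
             p_complete_removal_given_poor)
  if (any(probs < 0 | probs > 1))
    stop_hfoloc("hfoloc_invalid_argument", "probabilities must lie in [0,1]")
  if (length(region_vocabulary) == 0)
    stop_hfoloc("hfoloc_invalid_argument", "region_vocabulary: must be non-empty")
  structure(list(n_patients = as.integer(n_patients),
                 p_seizure_free = p_seizure_free,
                 region_vocabulary = region_vocabulary,
                 p_complete_removal_given_good = p_complete_removal_given_good,
                 p_complete_removal_given_poor = p_complete_removal_given_poor,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_columns <- c("Patient", "Sex/Age", "Onset/Fre", "Electrode", "PET-MRI",
                    "FLAWS", "HFOs", "Overlapped", "Removing", "Outcome")

#' Generate a synthetic patient cohort table
#'
#' One row per patient with modality-marked region sets (PET-MRI, FLAWS,
#' HFOs), their overlap, the removed set, marked-channel counts
#' (removed / non-removed per modality), coverage and completeness flags,
#' and an Engel outcome. The complete-removal flag is drawn conditionally on
#' outcome with the configured probabilities, so cohort-level association
#' tests have known structure.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with the standard cohort columns plus bookkeeping
#'   columns (`hfo_completely_removed`, `electrodes_cover_all_imaging`,
#'   `ChannRem.*`, `ChannNonRem.*`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  base <- data.frame(matrix(character(0), nrow = 0, ncol = length(cohort_columns)),
                     stringsAsFactors = FALSE)
  names(base) <- cohort_columns
  extra <- data.frame(hfo_completely_removed = logical(0),
                      electrodes_cover_all_imaging = logical(0),
                      `ChannRem.HFOs` = integer(0), `ChannNonRem.HFOs` = integer(0),
                      check.names = FALSE)
  if (n == 0) return(cbind(base, extra))
  vocab <- spec$region_vocabulary
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    good <- stats::runif(1) < spec$p_seizure_free
    outcome <- if (good) "I" else sample(c("II", "III"), 1)
    hfo <- sort(sample(vocab, sample(1:min(3, length(vocab)), 1)))
    pet <- sort(unique(c(sample(hfo, 1),
                         sample(vocab, sample(0:2, 1)))))
    flaws <- sort(unique(c(sample(hfo, 1),
                           sample(vocab, sample(0:1, 1)))))
    p_comp <- if (good) spec$p_complete_removal_given_good
              else spec$p_complete_removal_given_poor
    complete <- stats::runif(1) < p_comp
    removed <- if (complete) hfo else {
      drop <- sample(seq_along(hfo), 1)
      if (length(hfo) > 1) hfo[-drop] else character(0)
    }
    n_marked <- length(hfo) * sample(2:6, 1)       # channels per marked region
    n_rem <- if (complete) n_marked else round(n_marked * stats::runif(1, 0.2, 0.8))
    covered <- stats::runif(1) < 0.85
    rows[[i]] <- data.frame(
      Patient = i,
      `Sex/Age` = paste0(sample(c("M", "F"), 1), "/", sample(10:45, 1)),
      `Onset/Fre` = paste0(sample(1:20, 1), "/", sample(c("d", "w", "m"), 1)),
      Electrode = "SEEG",
      `PET-MRI` = paste(pet, collapse = ","),
      FLAWS = paste(flaws, collapse = ","),
      HFOs = paste(hfo, collapse = ","),
      Overlapped = paste(sort(intersect(pet, hfo)), collapse = ","),
      Removing = if (length(removed)) paste(removed, collapse = ",") else "Normal",
      Outcome = outcome,
      hfo_completely_removed = complete,
      electrodes_cover_all_imaging = covered,
      `ChannRem.HFOs` = as.integer(n_rem),
      `ChannNonRem.HFOs` = as.integer(n_marked - n_rem),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Write a cohort table to CSV with the standard column names
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
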
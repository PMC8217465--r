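fs <- 4096

test_that("zero-phase bandpass keeps passband amplitude and timing", {
  t <- seq_len(2 * fs) / fs
  x <- sin(2 * pi * 150 * t)
  y <- bandpass_zero_phase(x, fs, c(80, 200))
  core <- 2000:6000                        # away from edges
  expect_gt(max(abs(y[core])), 0.95)
  expect_lt(max(abs(y[core])), 1.05)
  # peak-time shift <= 1 sample
  px <- extract_peaks(x[core])$times
  py <- extract_peaks(y[core])$times
  shift <- vapply(px, function(i) min(abs(py - i)), 1)
  expect_lte(max(shift), 1)

  # stopband attenuation >= 20 dB at 50 Hz
  x50 <- sin(2 * pi * 50 * t)
  y50 <- bandpass_zero_phase(x50, fs, c(80, 200))
  expect_lt(20 * log10(sd(y50[core]) / sd(x50[core])), -20)

  expect_identical(bandpass_zero_phase(numeric(1000) , fs, c(80, 200)),
                   numeric(1000))
  expect_error(bandpass_zero_phase(x, fs, c(80, 3000)),
               class = "hfoloc_invalid_argument")
})

test_that("peak extraction counts half-cycle maxima of |signal|", {
  for (f0 in c(100, 150, 320)) {
    t <- seq_len(2 * fs) / fs
    pk <- extract_peaks(sin(2 * pi * f0 * t))
    expect_lt(abs(length(pk$times) - 2 * f0 * 2), 3)
    expect_true(all(diff(pk$times) > 0))
  }
  expect_length(extract_peaks(numeric(100))$times, 0)
  tri <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50)[-1])
  pk <- extract_peaks(tri)
  expect_equal(pk$times, 50L)
})

test_that("PPDC turning point separates baseline peaks from event peaks", {
  # constant amplitudes: flat chord is degenerate, mean = a, floored sd
  pk <- structure(list(times = seq(1, 20000, by = 100),
                       amplitudes = rep(2, 200)), class = "peak_series")
  bl <- ppdc_baseline(pk, 20480, fs)
  expect_equal(bl$mean[1], 2)
  expect_equal(bl$sd[1], 0.05 * 2)        # degenerate sd floor
  expect_equal(bl$turning_index[1], bl$n_peaks[1])

  # bimodal: 95% near 1, 5% near 12 -> baseline mean inside the low mode
  set.seed(31)
  amps <- c(runif(190, 0.8, 1.2), runif(10, 11, 13))
  pk2 <- structure(list(times = sort(sample(20000, 200)),
                        amplitudes = sample(amps)), class = "peak_series")
  bl2 <- ppdc_baseline(pk2, 20480, fs)
  expect_gt(bl2$mean[1], 0.9)
  expect_lt(bl2$mean[1], 1.1)
  expect_lte(bl2$turning_index[1], 191)

  # pure-noise channel: baseline mean within 15% of the all-peak mean
  rec <- make_background(duration = 20, seed = 32)
  filt <- bandpass_zero_phase(rec$samples[, 1], fs, c(80, 200))
  pk3 <- extract_peaks(filt)
  bl3 <- ppdc_baseline(pk3, nrow(rec$samples), fs)
  rel <- abs(bl3$mean - mean(pk3$amplitudes)) / mean(pk3$amplitudes)
  # the chord knee lands near the 0.88 amplitude quantile on 1/f-band noise,
  # so the baseline sits 13-19% below the all-peak mean
  expect_lt(max(rel), 0.25)
  expect_lt(mean(rel), 0.20)

  empty <- structure(list(times = integer(0), amplitudes = numeric(0)),
                     class = "peak_series")
  expect_error(ppdc_baseline(empty, 20480, fs),
               class = "hfoloc_degenerate_baseline")
})

test_that("candidate detection applies the nested run thresholds", {
  rec <- make_background(duration = 20, seed = 33)
  # planted 12x burst: exactly one ripple candidate with >= 80% span overlap
  ev <- burst_event(onset = 8, frequency = 150, n_cycles = 12, amplitude = 12)
  rec1 <- insert_oscillation(rec, ev)
  tab <- detect_hfos(rec1)
  rip <- tab[tab$band == "ripple", ]
  expect_equal(nrow(rip), 1)
  # the detected event lies inside the true span (taper edges stay below
  # threshold, so the true span is only partially covered)
  expect_gte(overlap_frac(rip$start_s, rip$end_s, 8, 8 + 0.08), 0.80)
  expect_gte(overlap_frac(8, 8 + 0.08, rip$start_s, rip$end_s), 0.50)
  expect_true(rip$retained)
  expect_gte(rip$n_peaks_long, 8)
  expect_gte(rip$n_peaks_short, 6)

  # 3-cycle burst: six absolute peaks < the eight required -> no candidate
  short <- insert_oscillation(rec, burst_event(onset = 8, frequency = 150,
                                               n_cycles = 3, amplitude = 12))
  expect_equal(nrow(detect_hfos(short)), 0)

  # 5x burst passes 3 SD but not 10 SD -> no ripple candidate
  weak <- insert_oscillation(rec, burst_event(onset = 8, frequency = 150,
                                              n_cycles = 12, amplitude = 5))
  wtab <- detect_hfos(weak)
  expect_equal(sum(wtab$band == "ripple"), 0)
})

test_that("candidate runs match a brute-force scan on short signals", {
  params <- detection_params()
  for (seed in 1:5) {
    rec <- make_background(duration = 2, seed = 100 + seed)
    rec <- insert_oscillation(rec, burst_event(onset = runif(1, 0.3, 1.5),
                                               frequency = 140, n_cycles = 12,
                                               amplitude = runif(1, 8, 14)))
    filt <- bandpass_zero_phase(rec$samples[, 1], fs, c(80, 200))
    pk <- extract_peaks(filt)
    bl <- ppdc_baseline(pk, nrow(rec$samples), fs, params)
    got <- detect_candidates(pk, bl, "ripple", fs, params, channel = "A1")
    want <- brute_force_candidates(pk, bl, "ripple", fs, params)
    expect_equal(nrow(got), length(want))
    if (nrow(got) > 0 && length(want) > 0) {
      expect_equal(got$start_s, vapply(want, `[[`, 0, "start"))
      expect_equal(got$end_s, vapply(want, `[[`, 0, "end"))
    }
  }
})

test_that("Gibbs discriminator keeps oscillations and rejects spikes", {
  rec <- make_background(duration = 10, seed = 34)
  # genuine 150 Hz burst at 10x SD: positive power difference
  recb <- insert_oscillation(rec, burst_event(onset = 5, frequency = 150,
                                              n_cycles = 12, amplitude = 10))
  seg <- recb$samples[round(4.95 * fs):round(5.15 * fs), 1]
  g <- gibbs_power_difference(seg, fs, c(80, 200))
  expect_gt(g$delta, 0)
  expect_true(g$keep)
  expect_lt(abs(g$f_star - 150), 15)

  # monophasic spike: monotone in-band spectrum, delta < 0
  recs <- insert_transient(rec, spike_event(onset = 5, amplitude = 15))
  segs <- recs$samples[round(4.95 * fs):round(5.15 * fs), 1]
  gs <- gibbs_power_difference(segs, fs, c(80, 200))
  expect_lt(gs$delta, 0)
  expect_false(gs$keep)

  # pure in-band sinusoid with no noise is kept
  t <- seq_len(fs) / fs
  gp <- gibbs_power_difference(sin(2 * pi * 150 * t), fs, c(80, 200))
  expect_true(gp$keep)

  expect_error(gibbs_power_difference(rnorm(100), fs, c(80, 200)),
               class = "hfoloc_invalid_argument")
})

test_that("sharp high-amplitude spikes become candidates but are never retained", {
  rec <- make_background(duration = 20, seed = 35)
  for (on in c(3, 8, 13)) {
    rec <- insert_transient(rec, spike_event(onset = on, amplitude = 50,
                                             width = 0.012))
  }
  tab <- detect_hfos(rec)
  expect_gt(nrow(tab), 0)                  # ringing does trip the thresholds
  expect_true(all(!tab$retained))
  expect_true(all(tab$gibbs_delta < 0))
})

test_that("detection is scale invariant and empty on zero input", {
  rec <- make_background(duration = 20, seed = 36)
  rec <- insert_oscillation(rec, burst_event(onset = 7, frequency = 130,
                                             n_cycles = 12, amplitude = 12))
  rec <- insert_oscillation(rec, burst_event(onset = 14, frequency = 320,
                                             n_cycles = 12, amplitude = 12))
  t1 <- detect_hfos(rec)
  scaled <- rec
  scaled$samples <- rec$samples * 7.3
  t2 <- detect_hfos(scaled)
  expect_equal(t1$start_s, t2$start_s)
  expect_equal(t1$end_s, t2$end_s)
  expect_equal(t1$retained, t2$retained)

  zero <- ieeg_recording(matrix(0, nrow = fs * 6, ncol = 1), fs, "A1")
  expect_warning(expect_warning(tz <- detect_hfos(zero), "degenerate"),
                 "degenerate")   # one warning per band
  expect_equal(nrow(tz), 0)
})

test_that("raising SD multipliers never increases retained events", {
  rec <- make_background(duration = 30, seed = 37)
  set.seed(37)
  for (i in 1:6) {
    rec <- insert_oscillation(rec, burst_event(onset = 2 + 4 * (i - 1),
                                               frequency = runif(1, 100, 180),
                                               n_cycles = 12,
                                               amplitude = runif(1, 8, 16)))
  }
  counts <- vapply(c(8, 10, 12, 16), function(mult) {
    p <- detection_params(ripple_short_run_sd = mult)
    sum(detect_hfos(rec, p)$retained)
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("channel rates are retained-count per minute with zero-filled channels", {
  ev <- data.frame(channel = c("A1", "A1", "A2"), band = "ripple",
                   start_s = c(1, 2, 3), end_s = c(1.1, 2.1, 3.1),
                   n_peaks_long = 10L, n_peaks_short = 7L,
                   peak_amplitude = 50, gibbs_delta = 1,
                   retained = c(TRUE, TRUE, FALSE))
  r <- channel_rates(ev, duration_s = 300, channels = c("A1", "A2", "A3"))
  rip <- r[r$band == "ripple", ]
  expect_equal(rip$rate_per_min[rip$channel == "A1"], 2 / 5)
  expect_equal(rip$rate_per_min[rip$channel == "A2"], 0)
  expect_equal(rip$rate_per_min[rip$channel == "A3"], 0)
  # ten events in five minutes -> 2/min
  ev10 <- ev[rep(1, 10), ]; ev10$retained <- TRUE
  r10 <- channel_rates(ev10, duration_s = 300, channels = "A1")
  expect_equal(r10$rate_per_min[r10$channel == "A1" & r10$band == "ripple"], 2)
  expect_error(channel_rates(ev, duration_s = 0, channels = "A1"),
               class = "hfoloc_invalid_argument")
})

test_that("parameter validation names the offending field", {
  expect_error(detection_params(ripple_band = c(200, 80)), "ripple_band")
  expect_error(detection_params(fr_band = c(150, 500)), "non-overlapping")
  expect_error(detection_params(short_run_peaks = 10, long_run_peaks = 8),
               "short_run_peaks")
  expect_error(detection_params(long_run_sd = -1),
               class = "hfoloc_invalid_argument")
})
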
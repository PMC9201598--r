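test_that("normalized spectra integrate to one and sort tones into bands", {
  set.seed(31)
  fs <- 1000
  x <- pink_noise(40 * fs, sd = 0.1)
  ss <- welch_band_power(x, fs)
  integral <- sum(diff(ss$psd$freq) *
    (head(ss$psd$density, -1) + tail(ss$psd$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_true(all(ss$psd$density >= 0))

  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t) + rnorm(length(t), sd = 0.05)
  bp <- welch_band_power(tone, fs)$band_powers
  expect_gt(
    bp$power[bp$band == "alpha_theta"],
    max(bp$power[bp$band != "alpha_theta"])
  )

  expect_error(welch_band_power(rnorm(3000), 1000), class = "lamindev_length_error")
})

test_that("detector agrees with an independent brute-force oracle", {
  x <- make_burst_trace(
    duration = 60, onsets = c(10, 25, 40), dur = c(0.5, 0.8, 0.4),
    freq = c(10, 15, 20), amp = 1, noise_sd = 0.1, seed = 32
  )
  got <- detect_spindle_bursts(x, 1000)
  want <- oracle_detect(x, 1000)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$onset_s, want$onset, tolerance = 1e-9)
  expect_equal(got$duration_s, want$duration, tolerance = 1e-9)
  expect_equal(got$trough_count, want$troughs)
  expect_equal(got$intra_freq_hz, got$trough_count / got$duration_s)
})

test_that("single planted burst at high SNR yields one event near 10 Hz", {
  x <- make_burst_trace(
    duration = 60, onsets = 20, dur = 0.3, freq = 10,
    amp = 1, noise_sd = 0.1, seed = 33
  )
  ev <- detect_spindle_bursts(x, 1000)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_s - 20), 0.1)
  expect_gte(ev$trough_count, 3)
  # one trough more or less moves a 0.3 s event by ~3 Hz: tolerance reflects
  # that granularity
  expect_equal(ev$intra_freq_hz, 10, tolerance = 0.2)
  expect_equal(ev$intra_freq_hz, ev$trough_count / ev$duration_s)
})

test_that("sub-100 ms and sub-3-trough bursts are discarded", {
  short <- make_burst_trace(
    duration = 60, onsets = 20, dur = 0.08, freq = 25,
    amp = 1, noise_sd = 0.05, seed = 34
  )
  ev_s <- detect_spindle_bursts(short, 1000)
  expect_true(all(ev_s$duration_s >= 0.1)) # nothing below the duration rule
  expect_equal(nrow(ev_s), 0)

  # 150 ms at 15 Hz has only 2 carrier troughs: screened out
  few <- make_burst_trace(
    duration = 60, onsets = 20, dur = 0.15, freq = 15,
    amp = 1, noise_sd = 0.05, seed = 35
  )
  ev_f <- detect_spindle_bursts(few, 1000)
  expect_equal(nrow(ev_f), 0)
})

test_that("detector is invariant to a DC offset", {
  x <- make_burst_trace(duration = 30, onsets = 12, dur = 0.5, freq = 12, seed = 36)
  a <- detect_spindle_bursts(x, 1000)
  b <- detect_spindle_bursts(x + 3.7, 1000)
  expect_equal(a$onset_s, b$onset_s)
  expect_equal(a$trough_count, b$trough_count)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-6)
})

test_that("spindle-burst statistics follow their definitions", {
  ev <- tibble::tibble(
    onset_s = c(1, 10, 20, 30, 40, 50), duration_s = rep(0.5, 6),
    trough_count = rep(5L, 6), intra_freq_hz = rep(10, 6),
    peak_envelope_mv = rep(1, 6)
  )
  st <- sb_stats(ev, 60)
  expect_equal(st$rate_per_min, 6)
  expect_equal(st$mean_intra_freq_hz, 10) # 5 troughs / 0.5 s
  expect_equal(st$pct_time_in_events, 100 * 3 / 60)

  empty <- ev[0, ]
  st0 <- sb_stats(empty, 60)
  expect_equal(st0$rate_per_min, 0)
  expect_equal(st0$pct_time_in_events, 0)
  expect_true(is.na(st0$mean_duration_s))

  bad <- ev
  bad$onset_s[6] <- 59.9
  expect_error(sb_stats(bad, 60), class = "lamindev_consistency_error")
})

test_that("event spectrograms average per-event wavelet maps", {
  x <- make_burst_trace(
    duration = 80, onsets = seq(5, 72, length.out = 20), dur = 0.5,
    freq = 10, amp = 1, noise_sd = 0.1, seed = 37
  )
  ev <- detect_spindle_bursts(x, 1000)
  expect_gte(nrow(ev), 12)
  sg <- event_spectrogram(x, 1000, ev, window = 0.6)
  peak_f <- sg$freqs[which.max(apply(sg$magnitude, 1, max))]
  expect_gte(peak_f, 5)
  expect_lte(peak_f, 15)

  one <- event_spectrogram(x, 1000, ev[1, ], window = 0.6)
  i0 <- round(ev$onset_s[1] * 1000) + 1
  direct <- morlet_cwt(x[i0:(i0 + 599)], 1000)
  expect_equal(one$magnitude, direct$magnitude)
  expect_equal(one$n_events, 1)

  late <- ev[1, ]
  late$onset_s <- 79.9 # window falls off the record end
  expect_error(
    suppressWarnings(event_spectrogram(x, 1000, late, window = 0.6)),
    class = "lamindev_empty_error"
  )
  expect_error(event_spectrogram(x, 1000, ev[0, ]), class = "lamindev_empty_error")
})

test_that("baseline firing rate averages 500 ms windows correctly", {
  expect_equal(baseline_firing_rate(numeric(0), 60), 0)
  train <- seq(0.05, 59.95, by = 0.1) # regular 10 Hz
  expect_equal(baseline_firing_rate(train, 60), 10, tolerance = 0.1)
  set.seed(38)
  pois <- sort(runif(3000, 0, 600)) # homogeneous 5 Hz over 600 s
  est <- baseline_firing_rate(pois, 600)
  expect_equal(est, length(pois) / 600, tolerance = 1e-9) # tiling windows
  expect_error(baseline_firing_rate(c(-1, 2), 60), class = "lamindev_validation_error")
})
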
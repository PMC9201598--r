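test_that("generation is fully deterministic given (config, seed)", {
  cf <- small_config(seed = 61, baseline_s = 10)
  a <- generate_recording(cf)
  b <- generate_recording(cf)
  expect_identical(a$recording$lfp, b$recording$lfp)
  expect_identical(a$recording$spike_times, b$recording$spike_times)
  expect_identical(a$stimuli, b$stimuli)
  expect_identical(a$truth$planted_bursts, b$truth$planted_bursts)
  c <- generate_recording(small_config(seed = 62, baseline_s = 10))
  expect_false(identical(a$recording$lfp, c$recording$lfp))
})

test_that("config guards reject non-monotone speed maps and bad PPRs", {
  expect_error(
    generator_config(speed_amplitudes_mv = c(5, 4, 3, 2, 1)),
    class = "lamindev_config_error"
  )
  expect_error(
    generator_config(speed_latencies_s = c(0.01, 0.02, 0.03, 0.04, 0.05)),
    class = "lamindev_config_error"
  )
  expect_error(generator_config(isi_pprs = c(2, 0.5, 0.8, 0.6, 0.4)),
    class = "lamindev_config_error"
  )
})

test_that("stimulus layout follows the block protocol", {
  out <- generate_recording(small_config(seed = 63, baseline_s = 5))
  stim <- out$stimuli
  expect_silent(validate_stimulus_table(stim))
  singles <- stim[stim$kind == "single", ]
  expect_equal(sort(unique(singles$speed_hz)), c(5, 10, 20, 40, 80))
  expect_true(all(table(singles$block) == 3))
  paired <- stim[stim$kind == "paired", ]
  expect_equal(sort(unique(paired$isi_s)), c(0.1, 0.25, 0.5, 1, 1.5))
  for (b in unique(paired$block)) {
    on <- paired$onset_s[paired$block == b]
    expect_equal(diff(on)[seq(1, length(on) - 1, by = 2)],
      rep(paired$isi_s[paired$block == b][1], length(on) / 2),
      tolerance = 1e-9
    )
  }
})

test_that("planted bursts round-trip through the detector", {
  out <- generate_recording(baseline_config(seed = 65))
  truth <- out$truth$planted_bursts
  expect_gt(nrow(truth), 1)
  # detection runs on the burst-carrying channel average, as in the pipeline
  sig <- colMeans(out$recording$lfp[out$truth$burst_channels, seq_len(60 * 1000)])
  ev <- detect_spindle_bursts(sig, 1000)
  # every planted burst has a detection within 100 ms
  match <- vapply(truth$onset_s, function(on) {
    any(abs(ev$onset_s - on) <= 0.1)
  }, logical(1))
  expect_gte(mean(match), 0.8)
  matched <- ev[vapply(ev$onset_s, function(on) {
    any(abs(truth$onset_s - on) <= 0.1)
  }, logical(1)), ]
  freq_true <- truth$freq_hz[vapply(
    matched$onset_s,
    function(on) which.min(abs(truth$onset_s - on)), integer(1)
  )]
  expect_lt(median(abs(matched$intra_freq_hz - freq_true) / freq_true), 0.15)
})

test_that("zero-noise recordings reproduce planted evoked templates exactly", {
  out <- generate_recording(evoked_config(seed = 65, noise_sd_mv = 0))
  centre <- out$truth$granular_center
  sig <- out$recording$lfp[centre, ]
  for (i in seq_len(nrow(out$truth$evoked_templates))) {
    tmpl <- out$truth$evoked_templates[i, ]
    ons <- out$stimuli$onset_s[out$stimuli$speed_hz == tmpl$speed_hz &
      out$stimuli$kind == "single"]
    pk <- peak_metrics(average_evoked(sig, 1000, ons), search_window = c(0, 0.12))
    expect_equal(pk$amplitude, tmpl$amplitude_mv, tolerance = 1e-12)
    expect_equal(pk$latency_ms, 1000 * tmpl$latency_s, tolerance = 1e-12)
  }
})

test_that("measured PPR equals the prescribed ratio at zero noise", {
  out <- generate_recording(small_config(
    seed = 66, baseline_s = 2, noise_sd_mv = 0,
    burst_rate_per_min = 0
  ))
  sig <- out$recording$lfp[out$truth$granular_center, ]
  paired <- out$stimuli[out$stimuli$kind == "paired", ]
  for (b in unique(paired$block)) {
    rows <- paired[paired$block == b, ]
    isi <- rows$isi_s[1]
    firsts <- rows$onset_s[seq(1, nrow(rows), by = 2)]
    avg <- average_evoked(sig, 1000, firsts, window = c(-0.15, isi + 0.3))
    pp <- paired_pulse_ratio(avg$mean, 1000, 0.15, 0.15 + isi,
      search_window = min(0.1, isi)
    )
    want <- out$truth$prescribed_ppr$ppr[out$truth$prescribed_ppr$isi_s == isi]
    expect_equal(pp$ppr, want, tolerance = 0.02)
  }
})

test_that("cohort generation labels groups and respects age ranges", {
  profiles <- age_group_profiles(
    n_channels = 8, baseline_s = 2, trials_per_block = 2,
    iti_s = 1.2, include_paired = FALSE, granular_center = 4
  )
  cohort <- generate_cohort(profiles, n_per_group = 2,
    age_ranges = list(CP = c(5, 8), preAW = c(9, 11), AW = c(12, 16)),
    seed = 67
  )
  expect_length(cohort, 6)
  groups <- vapply(cohort, `[[`, character(1), "group")
  expect_equal(groups, rep(c("CP", "preAW", "AW"), each = 2))
  ages <- vapply(cohort, function(s) s$recording$age_days, numeric(1))
  expect_true(all(ages[1:2] %in% 5:8))
  expect_true(all(ages[5:6] %in% 12:16))
  expect_error(generate_cohort(profiles[1], 2), class = "lamindev_config_error")
  expect_error(generate_cohort(profiles, 0), class = "lamindev_config_error")
})
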
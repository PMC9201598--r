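test_that("trial averaging reproduces a noise-free template exactly", {
  fs <- 1000
  x <- numeric(30 * fs)
  tmpl_t <- seq(0, 0.2 - 1 / fs, by = 1 / fs)
  tmpl <- -0.4 * exp(-((tmpl_t - 0.025)^2) / (2 * 0.008^2))
  onsets <- seq(2, 26, by = 2)
  for (on in onsets) {
    k <- round(on * fs) + seq_along(tmpl)
    x[k] <- x[k] + tmpl
  }
  resp <- average_evoked(x, fs, onsets)
  sel <- resp$time >= 0 & resp$time < 0.2
  expect_equal(resp$mean[sel], tmpl)
  expect_equal(resp$n_trials, length(onsets))

  # a DC offset disappears with the pre-stimulus baseline
  resp_dc <- average_evoked(x + 0.1, fs, onsets)
  expect_equal(resp_dc$mean, resp$mean, tolerance = 1e-12)

  expect_error(average_evoked(x, fs, numeric(0)), class = "lamindev_empty_error")
})

test_that("noisy trial averages converge to the template at the 1/sqrt(n) rate", {
  fs <- 1000
  set.seed(41)
  n_tr <- 100
  noise_sd <- 0.4
  tmpl_t <- seq(0, 0.2 - 1 / fs, by = 1 / fs)
  tmpl <- -0.4 * exp(-((tmpl_t - 0.025)^2) / (2 * 0.008^2))
  onsets <- seq(2, by = 1, length.out = n_tr)
  x <- rnorm((n_tr + 4) * fs, sd = noise_sd)
  for (on in onsets) {
    k <- round(on * fs) + seq_along(tmpl)
    x[k] <- x[k] + tmpl
  }
  resp <- average_evoked(x, fs, onsets)
  sel <- resp$time >= 0 & resp$time < 0.2
  # pointwise within 3 SE plus the baseline-subtraction jitter
  se <- noise_sd / sqrt(n_tr)
  expect_lt(max(abs(resp$mean[sel] - tmpl)), 5 * se)
})

test_that("PSTH counts, smooths and baseline-corrects as specified", {
  onsets <- seq(1, 20, by = 1)
  spikes <- onsets + 0.0105 # one spike at +10.5 ms (bin centre) per trial
  ps <- compute_psth(spikes, onsets)
  hot <- which(ps$counts > 0)
  expect_length(hot, 1)
  expect_equal(ps$counts[hot], 20)
  expect_equal(ps$time[hot], 0.0105)
  expect_equal(sum(ps$counts), 20) # conservation pre-smoothing
  # 5 ms boxcar spreads the mass over five bins, preserving the total
  rate_bins <- which(ps$rate_smoothed > 0)
  expect_length(rate_bins, 5)
  expect_equal(sum(ps$rate_smoothed) * 0.001 * 20, 20, tolerance = 1e-9)

  expect_error(compute_psth(spikes, onsets, smooth = 0.004),
    class = "lamindev_config_error"
  )
})

test_that("stationary Poisson spiking gives a PSTH centred on zero", {
  set.seed(42)
  dur <- 400
  spikes <- sort(runif(5 * dur, 0, dur))
  onsets <- seq(5, dur - 5, by = 2)[1:150]
  ps <- compute_psth(spikes, onsets)
  # mean of the baseline-subtracted PSTH over the window ~ 0 within 3 SE of
  # the dominant (100 ms baseline) counting error
  se <- sqrt(5 / (length(onsets) * 0.1)) + sqrt(5 / (length(onsets) * 0.6))
  expect_lt(abs(mean(ps$mean)), 3 * se)
})

test_that("peak metrics honour polarity, ties and degenerate input", {
  tm <- seq(-0.1, 0.5, by = 1e-3)
  y <- numeric(length(tm))
  y[which.min(abs(tm - 0.024)):which.min(abs(tm - 0.026))] <- -0.4
  r <- list(time = tm, mean = y, kind = "lfp")
  pk <- peak_metrics(r)
  expect_equal(pk$amplitude, 0.4)
  expect_equal(pk$latency_ms, 24) # earliest sample of the flat extremum

  y2 <- numeric(length(tm))
  y2[which.min(abs(tm - 0.015))] <- 30
  pk2 <- peak_metrics(list(time = tm, mean = y2, kind = "mua"))
  expect_equal(pk2$amplitude, 30)
  expect_equal(pk2$latency_ms, 15)

  y3 <- numeric(length(tm))
  y3[which.min(abs(tm - 0.020))] <- -1
  y3[which.min(abs(tm - 0.040))] <- -1
  expect_equal(peak_metrics(list(time = tm, mean = y3, kind = "lfp"))$latency_ms, 20)

  flat <- peak_metrics(list(time = tm, mean = rep(1, length(tm)), kind = "lfp"))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$latency_ms))
})

test_that("paired-pulse ratio divides second by first peak", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  bump <- function(at, amp) -amp * exp(-((t - at)^2) / (2 * 0.008^2))
  x <- bump(0.53, 1.0) + bump(1.03, 0.5)
  pp <- paired_pulse_ratio(x, fs, onset1 = 0.5, onset2 = 1.0)
  expect_equal(pp$ppr, 0.5, tolerance = 1e-6)
  expect_false(pp$failure)

  x2 <- bump(0.53, 1.0) + bump(1.03, 1.0)
  expect_equal(paired_pulse_ratio(x2, fs, 0.5, 1.0)$ppr, 1, tolerance = 1e-6)

  # absent second response over residual slow ripple: failure flag, low ppr
  x3 <- bump(0.53, 1.0) + 0.01 * sin(2 * pi * 10 * t)
  pp3 <- paired_pulse_ratio(x3, fs, 0.5, 1.0)
  expect_true(pp3$failure)
  expect_lt(pp3$ppr, 0.1)

  # a first response below the noise floor cannot normalize
  set.seed(44)
  x4 <- rnorm(length(t), sd = 0.5)
  expect_error(paired_pulse_ratio(x4, fs, 0.5, 1.0),
    class = "lamindev_undefined_ppr_error"
  )
})

test_that("condition aggregation reports subject-level mean, SEM and N", {
  metrics <- tidyr::expand_grid(
    subject_id = paste0("s", 1:5),
    condition = c("5", "10")
  ) |>
    dplyr::mutate(
      genotype = "WT", age_window = "CP", layer = "G",
      amplitude = rep(c(0.2, 0.4), 5)
    )
  agg <- condition_aggregate(metrics, "amplitude")
  expect_equal(nrow(agg), 2)
  expect_equal(agg$n, c(5, 5))
  expect_equal(agg$mean[agg$condition == "5"], 0.2)
  expect_equal(agg$sem, c(0, 0)) # identical values have zero SEM

  # a subject missing one condition reduces that cell's N
  sub <- metrics[-1, ]
  agg2 <- suppressMessages(condition_aggregate(sub, "amplitude"))
  expect_setequal(agg2$n, c(4, 5))

  expect_error(condition_aggregate(dplyr::select(metrics, -"layer"), "amplitude"),
    class = "lamindev_grouping_error"
  )
})
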
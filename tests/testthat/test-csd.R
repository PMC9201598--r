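test_that("three-point Hamming filter matches its defining weights", {
  expect_equal(hamming_smooth(c(2, 2, 2, 2)), c(2, 2, 2, 2))
  expect_equal(hamming_smooth(c(0, 1, 0)), c(0.23, 0.54, 0.23))
  # affine profiles are fixed points away from the padded boundary
  expect_equal(hamming_smooth(c(1, 2, 3, 4))[2:3], c(2, 3))
  expect_error(hamming_smooth(c(1, 2)), class = "lamindev_size_error")
})

test_that("Hamming smoothing never widens the profile range", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1))
    sm <- hamming_smooth(x)
    expect_lte(diff(range(sm)), diff(range(x)) + 1e-12)
  }
})

test_that("CSD of affine profiles vanishes and quadratics give 2/h^2", {
  depths <- 1:8
  affine <- 3 + 0.7 * depths
  out <- estimate_csd(affine, h = 1, vaknin = FALSE)
  expect_equal(max(abs(out$csd)), 0)
  # with Vaknin padding the interior stays exactly zero and size is preserved
  outv <- estimate_csd(affine, h = 1, vaknin = TRUE)
  expect_equal(nrow(outv$csd), 8)
  expect_equal(max(abs(outv$csd[2:7, ])), 0)

  quad <- depths^2
  outq <- estimate_csd(quad, h = 1, vaknin = FALSE)
  expect_equal(as.vector(outq$csd), rep(-2, 6)) # sinks-negative convention
  h <- 50
  outq2 <- estimate_csd((depths * h)^2, h = h, vaknin = FALSE)
  expect_equal(abs(as.vector(outq2$csd)), rep(2, 6)) # exact 2/h^2 magnitude
})

test_that("evoked_csd aligns, averages and inherits the probe geometry", {
  out <- generate_recording(evoked_config(seed = 21, noise_sd_mv = 0))
  ons <- out$stimuli$onset_s[out$stimuli$speed_hz == 80]
  csd <- evoked_csd(out$recording, ons, window = c(-0.05, 0.1), smooth = FALSE)
  expect_s3_class(csd, "csd_map")
  expect_equal(nrow(csd$csd), 12)
  expect_equal(csd$h, 50)
  # pre-stimulus CSD of a noise-free recording is exactly zero
  expect_equal(max(abs(csd$csd[, csd$time < 0])), 0)
  # the strongest sink sits at the planted granular centre at the planted latency
  peak <- which(csd$csd == min(csd$csd), arr.ind = TRUE)
  expect_equal(unname(peak[1, 1]), out$truth$granular_center)
  expect_equal(csd$time[peak[1, 2]], 0.03)
})

test_that("Vaknin correction preserves channel count; errors are typed", {
  prof <- matrix(rnorm(5 * 10), nrow = 5)
  expect_equal(nrow(estimate_csd(prof, h = 50)$csd), 5)
  expect_equal(nrow(estimate_csd(prof, h = 50, vaknin = FALSE)$csd), 3)
  expect_error(estimate_csd(prof, h = -1), class = "lamindev_geometry_error")
  expect_error(estimate_csd(matrix(c(1, Inf, 3), 3, 1), h = 1),
    class = "lamindev_numeric_error"
  )
  expect_error(estimate_csd(matrix(1:4, 2, 2), h = 1), class = "lamindev_size_error")
})

test_that("the CSD estimator is linear in the potential profile", {
  set.seed(12)
  p1 <- matrix(rnorm(12 * 30), 12)
  p2 <- matrix(rnorm(12 * 30), 12)
  for (smooth in c(FALSE, TRUE)) {
    lhs <- estimate_csd(2 * p1 - 3 * p2, h = 50, smooth = smooth)$csd
    rhs <- 2 * estimate_csd(p1, h = 50, smooth = smooth)$csd -
      3 * estimate_csd(p2, h = 50, smooth = smooth)$csd
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("pair averaging halves the profile and doubles the spacing", {
  prof <- matrix(rep(c(1, 3, 5, 7, 9, 11), 4), nrow = 6)
  out <- estimate_csd(prof, h = 25, pair_average = TRUE, vaknin = FALSE)
  expect_equal(nrow(out$csd), 1)
  expect_equal(out$h, 50)
  expect_equal(as.vector(out$csd), rep(0, 4)) # affine pairs stay affine
})

test_that("layer assignment follows the earliest large sink", {
  tm <- seq(0, 0.1, by = 1e-3)
  mk_map <- function(csd) {
    structure(
      list(
        csd = csd, time = tm, depth_index = seq_len(nrow(csd)),
        h = 50, sinks_negative = TRUE
      ),
      class = "csd_map"
    )
  }
  sink_wave <- function(lat, amp) -amp * exp(-((tm - lat)^2) / (2 * 0.005^2))

  csd <- matrix(0, nrow = 24, ncol = length(tm))
  for (ch in 14:17) csd[ch, ] <- sink_wave(0.02, 1)
  la <- assign_layers(mk_map(csd))
  expect_equal(la$granular_channels, 14:17)
  expect_equal(la$supragranular_channels, 1:13)
  expect_equal(la$infragranular_channels, 18:24)
  expect_equal(la$sink_latency_ms, 20)

  # an earlier but sub-criterion deep sink must lose to the large one
  csd2 <- matrix(0, nrow = 24, ncol = length(tm))
  csd2[20, ] <- sink_wave(0.01, 0.1)
  csd2[10, ] <- sink_wave(0.03, 1)
  la2 <- assign_layers(mk_map(csd2), amplitude_fraction = 0.5)
  expect_equal(la2$sink_channel, 10)

  expect_error(assign_layers(mk_map(matrix(0, 5, length(tm)))),
    class = "lamindev_no_sink_error"
  )
})

test_that("granular sink localization recovers the planted dipole across seeds", {
  hits <- 0L
  for (seed in 1:10) {
    out <- generate_recording(evoked_config(seed = seed))
    ons <- out$stimuli$onset_s[out$stimuli$speed_hz == 80]
    csd <- evoked_csd(out$recording, ons, smooth = TRUE)
    la <- assign_layers(csd, search_window = c(0, 0.1))
    centre <- mean(range(la$granular_channels))
    if (abs(centre - out$truth$granular_center) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
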
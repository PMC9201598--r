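# Synthetic laminar recordings with complete ground truth. The generator
# emulates the structure of a neonatal barrel-cortex session: a spontaneous
# baseline carrying intermittent 5-35 Hz spindle bursts over pink background
# noise, single-deflection blocks at five deflection speeds whose evoked
# dipole grows in amplitude and shortens in latency with speed, paired-pulse
# blocks with prescribed paired-pulse ratios per inter-stimulus interval,
# event/stimulus-modulated Poisson spiking, and optional 50 Hz contamination
# on designated bad channels.

#' Configuration for the synthetic-recording generator
#'
#' Defaults reproduce the experimental protocol the pipeline targets: blocks
#' of 20 trials, 30 s between trials, deflection speeds {5, 10, 20, 40, 80}
#' (rectified-sine width equivalents, Hz) with amplitude increasing and
#' latency decreasing with speed, paired-pulse ISIs {0.1, 0.25, 0.5, 1.0,
#' 1.5} s, and spontaneous spindle bursts (5-35 Hz carriers, 0.1-2 s) over
#' pink noise. Tests and examples pass smaller `trials_per_block` / `iti_s` /
#' `n_channels` to keep problem sizes desk-scale; the scientific parameters
#' (amplitudes, latencies, ratios, rates) are fixed here.
#'
#' @param n_channels Number of probe contacts.
#' @param h_um Vertical contact spacing, micrometers.
#' @param fs_lfp LFP sampling rate, Hz.
#' @param fs_spikes Acquisition clock for spike times, Hz (metadata).
#' @param baseline_s Spontaneous baseline length, s.
#' @param trials_per_block Trials per stimulus block.
#' @param iti_s Inter-trial interval, s.
#' @param speeds Deflection speed labels, Hz-equivalents.
#' @param speed_amplitudes_mv Evoked sink amplitude per speed at the granular
#'   centre channel, mV (strictly increasing).
#' @param speed_latencies_s Evoked peak latency per speed, s (strictly
#'   decreasing).
#' @param isis Paired-pulse inter-stimulus intervals, s.
#' @param isi_pprs Prescribed paired-pulse ratio per ISI (the CP-like
#'   "reverse-U": depression at short and long ISIs, maximum at 0.5 s).
#' @param include_paired Include the paired-pulse blocks.
#' @param burst_rate_per_min Spindle-burst rate over the baseline, events/min.
#' @param burst_freq_range Carrier frequency range, Hz.
#' @param burst_dur_range Burst duration range, s.
#' @param burst_amplitude_mv Burst envelope peak amplitude, mV.
#' @param noise_sd_mv Pink-noise SD, mV (0 = noise-free); envelope SNR is
#'   `burst_amplitude_mv / noise_sd_mv`.
#' @param pink_exponent Background-noise PSD exponent.
#' @param granular_center Granular sink centre channel.
#' @param granular_halfwidth Gaussian sink half-width, channels.
#' @param evoked_width_s Temporal width (SD) of the evoked transient, s.
#' @param baseline_rate_hz Baseline Poisson spike rate per channel, Hz.
#' @param evoked_peak_rate_hz Added spike rate at the evoked peak, Hz.
#' @param burst_rate_gain Multiplicative spike-rate gain during bursts.
#' @param line_noise_channels Channels carrying 50 Hz contamination.
#' @param line_amplitude_mv 50 Hz sinusoid amplitude, mV.
#' @param age_days Subject age, postnatal days.
#' @param genotype Group label.
#' @param seed Integer RNG seed; (config, seed) fully determines the output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_channels = 32, h_um = 50, fs_lfp = 1000,
                             fs_spikes = 30000, baseline_s = 120,
                             trials_per_block = 20, iti_s = 30,
                             speeds = c(5, 10, 20, 40, 80),
                             speed_amplitudes_mv = c(0.20, 0.30, 0.45, 0.65, 0.90),
                             speed_latencies_s = c(0.080, 0.065, 0.050, 0.040, 0.030),
                             isis = c(0.10, 0.25, 0.50, 1.00, 1.50),
                             isi_pprs = c(0.15, 0.50, 0.85, 0.60, 0.45),
                             include_paired = TRUE,
                             burst_rate_per_min = 6,
                             burst_freq_range = c(8, 25),
                             burst_dur_range = c(0.3, 1.5),
                             burst_amplitude_mv = 0.5,
                             noise_sd_mv = 0.1,
                             pink_exponent = 1,
                             granular_center = round(n_channels / 2),
                             granular_halfwidth = 1,
                             evoked_width_s = 0.010,
                             baseline_rate_hz = 2,
                             evoked_peak_rate_hz = 60,
                             burst_rate_gain = 4,
                             line_noise_channels = integer(0),
                             line_amplitude_mv = 0.5,
                             age_days = 7, genotype = "WT", seed = 1) {
  if (any(diff(speed_amplitudes_mv) <= 0) || any(diff(speed_latencies_s) >= 0)) {
    abort("speed map must increase in amplitude and decrease in latency",
      class = "lamindev_config_error"
    )
  }
  if (any(isi_pprs < 0 | isi_pprs > 1.5)) {
    abort("prescribed PPRs must lie in [0, 1.5]", class = "lamindev_config_error")
  }
  structure(as.list(environment()), class = "generator_config")
}

# Zero-sum laminar dipole profile: Gaussian sink at the granular centre
# (normalized to -1 there) with flanking half-amplitude sources rescaled so
# the spatial sum is exactly zero.
dipole_profile <- function(n_channels, center, halfwidth) {
  ch <- seq_len(n_channels)
  g <- exp(-(ch - center)^2 / (2 * halfwidth^2))
  up <- exp(-(ch - (center - 4 * halfwidth))^2 / (2 * (2 * halfwidth)^2))
  down <- exp(-(ch - (center + 4 * halfwidth))^2 / (2 * (2 * halfwidth)^2))
  a <- sum(g) / (sum(up) + sum(down))
  p <- -g + a * (up + down)
  p / abs(p[center])
}

#' Generate a synthetic laminar recording with ground truth
#'
#' @param config A [generator_config()].
#' @return List with `recording` (a [recording()]), `stimuli` (tibble), and
#'   `truth` (a `ground_truth` list: planted bursts, granular channel range,
#'   per-speed evoked templates, prescribed PPR per ISI, bad channels, noise
#'   parameters, seed).
#' @export
generate_recording <- function(config = generator_config()) {
  cf <- config
  set.seed(cf$seed)
  fs <- cf$fs_lfp

  # ---- stimulus layout -------------------------------------------------
  t_cursor <- cf$baseline_s
  stim <- list()
  block <- 0L
  for (sp in cf$speeds) {
    block <- block + 1L
    onsets <- t_cursor + cf$iti_s * seq(0, cf$trials_per_block - 1)
    stim[[length(stim) + 1]] <- tibble(
      onset_s = onsets, kind = "single", speed_hz = sp,
      isi_s = NA_real_, block = block
    )
    t_cursor <- onsets[length(onsets)] + cf$iti_s
  }
  if (cf$include_paired) {
    for (j in seq_along(cf$isis)) {
      block <- block + 1L
      # trial period = iti + isi so the inter-trial gap is measured from the
      # second deflection and trials can never collide at long ISIs
      first <- t_cursor + (cf$iti_s + cf$isis[j]) * seq(0, cf$trials_per_block - 1)
      onsets <- sort(c(first, first + cf$isis[j]))
      stim[[length(stim) + 1]] <- tibble(
        onset_s = onsets, kind = "paired", speed_hz = max(cf$speeds),
        isi_s = cf$isis[j], block = block
      )
      t_cursor <- first[length(first)] + cf$isis[j] + cf$iti_s
    }
  }
  stimuli <- dplyr::bind_rows(stim)
  duration <- ceiling(t_cursor + 1)
  n_samp <- round(duration * fs)
  if (nrow(stimuli) && max(stimuli$onset_s) + 0.6 > duration) {
    abort("stimulus layout exceeds recording duration", class = "lamindev_layout_error")
  }
  tvec <- (seq_len(n_samp) - 1) / fs

  # ---- LFP -------------------------------------------------------------
  lfp <- matrix(0, nrow = cf$n_channels, ncol = n_samp)
  if (cf$noise_sd_mv > 0) {
    for (i in seq_len(cf$n_channels)) {
      lfp[i, ] <- pink_noise(n_samp, exponent = cf$pink_exponent, sd = cf$noise_sd_mv)
    }
  }

  profile <- dipole_profile(cf$n_channels, cf$granular_center, cf$granular_halfwidth)
  granular_range <- which(-profile >= 0.5) # channels carrying >= half the sink

  # collect (onset, amplitude, latency) triples first, then add them to the
  # LFP in one loop in this frame: subassignment here is in place, whereas a
  # closure writing through `<<-` would copy the whole matrix per deflection
  evoked_events <- list()
  add_evoked <- function(onset, amp, latency) {
    evoked_events[[length(evoked_events) + 1]] <<- c(onset, amp, latency)
  }

  amp_of <- stats::setNames(cf$speed_amplitudes_mv, cf$speeds)
  lat_of <- stats::setNames(cf$speed_latencies_s, cf$speeds)
  ppr_of <- stats::setNames(cf$isi_pprs, cf$isis)

  singles <- stimuli[stimuli$kind == "single", ]
  for (r in seq_len(nrow(singles))) {
    sp <- as.character(singles$speed_hz[r])
    add_evoked(singles$onset_s[r], amp_of[[sp]], lat_of[[sp]])
  }
  paired <- stimuli[stimuli$kind == "paired", ]
  if (nrow(paired)) {
    sp <- as.character(max(cf$speeds))
    # rows alternate first/second deflection within each trial
    for (b in unique(paired$block)) {
      rows <- paired[paired$block == b, ]
      isi <- rows$isi_s[1]
      firsts <- rows$onset_s[seq(1, nrow(rows), by = 2)]
      for (on in firsts) {
        add_evoked(on, amp_of[[sp]], lat_of[[sp]])
        add_evoked(on + isi, ppr_of[[as.character(isi)]] * amp_of[[sp]], lat_of[[sp]])
      }
    }
  }
  for (evk in evoked_events) {
    onset <- evk[1]
    amp <- evk[2]
    latency <- evk[3]
    # support starts exactly at the deflection onset so pre-stimulus
    # baselines of noise-free recordings are exactly zero
    k0 <- round(onset * fs) + 1
    k1 <- round((onset + latency + 4 * cf$evoked_width_s) * fs) + 1
    k <- max(1, k0):min(n_samp, k1)
    kern <- exp(-((tvec[k] - onset - latency)^2) / (2 * cf$evoked_width_s^2))
    lfp[, k] <- lfp[, k] + amp * (profile %o% kern)
  }

  # ---- spindle bursts over the baseline --------------------------------
  n_bursts <- rpois(1, cf$burst_rate_per_min * cf$baseline_s / 60)
  burst_channels <- pmax(1, cf$granular_center - 3):pmin(cf$n_channels, cf$granular_center + 3)
  bursts <- tibble(
    onset_s = numeric(0), duration_s = numeric(0),
    freq_hz = numeric(0), amplitude_mv = numeric(0)
  )
  if (n_bursts > 0) {
    tries <- 0
    while (nrow(bursts) < n_bursts && tries < 50 * n_bursts) {
      tries <- tries + 1
      dur <- runif(1, cf$burst_dur_range[1], cf$burst_dur_range[2])
      freq <- runif(1, cf$burst_freq_range[1], cf$burst_freq_range[2])
      if (dur * freq < 4) next # too few cycles to count troughs
      hi <- cf$baseline_s - dur - 1
      if (hi <= 1) next # baseline too short for this burst
      on <- runif(1, 1, hi)
      if (nrow(bursts) && any(abs(bursts$onset_s - on) < bursts$duration_s + dur + 0.5)) next
      bursts <- dplyr::bind_rows(bursts, tibble(
        onset_s = on, duration_s = dur, freq_hz = freq,
        amplitude_mv = cf$burst_amplitude_mv
      ))
    }
    bursts <- bursts[order(bursts$onset_s), ]
    for (r in seq_len(nrow(bursts))) {
      k0 <- round(bursts$onset_s[r] * fs) + 1
      k1 <- min(n_samp, k0 + round(bursts$duration_s[r] * fs) - 1)
      k <- k0:k1
      tt <- (k - k0) / fs
      hann <- 0.5 * (1 - cos(2 * pi * tt / bursts$duration_s[r]))
      carrier <- sin(2 * pi * bursts$freq_hz[r] * tt)
      wave <- bursts$amplitude_mv[r] * hann * carrier
      lfp[burst_channels, k] <- lfp[burst_channels, k] +
        matrix(wave, nrow = length(burst_channels), ncol = length(k), byrow = TRUE)
    }
  }

  # ---- line noise ------------------------------------------------------
  for (bc in cf$line_noise_channels) {
    lfp[bc, ] <- lfp[bc, ] + cf$line_amplitude_mv * sin(2 * pi * 50 * tvec)
  }

  # ---- spikes: event/stimulus-modulated Poisson ------------------------
  spike_times <- vector("list", cf$n_channels)
  in_granular <- function(i) i %in% granular_range
  for (i in seq_len(cf$n_channels)) {
    layer_gain <- if (in_granular(i)) 1 else 0.4
    rate_max <- cf$baseline_rate_hz * cf$burst_rate_gain + cf$evoked_peak_rate_hz
    n_cand <- rpois(1, rate_max * duration)
    cand <- sort(runif(n_cand, 0, duration))
    lambda <- rep(cf$baseline_rate_hz, length(cand))
    if (nrow(bursts)) {
      for (r in seq_len(nrow(bursts))) {
        inb <- cand >= bursts$onset_s[r] & cand <= bursts$onset_s[r] + bursts$duration_s[r]
        lambda[inb] <- lambda[inb] * cf$burst_rate_gain
      }
    }
    if (in_granular(i)) {
      bump <- function(on, scale) {
        sel <- abs(cand - on) < 6 * cf$evoked_width_s
        lambda[sel] <<- lambda[sel] + scale * cf$evoked_peak_rate_hz *
          exp(-((cand[sel] - on)^2) / (2 * cf$evoked_width_s^2))
      }
      for (r in seq_len(nrow(singles))) {
        sp <- as.character(singles$speed_hz[r])
        bump(singles$onset_s[r] + lat_of[[sp]], amp_of[[sp]] / max(cf$speed_amplitudes_mv))
      }
      if (nrow(paired)) {
        sp <- as.character(max(cf$speeds))
        for (b in unique(paired$block)) {
          rows <- paired[paired$block == b, ]
          isi <- rows$isi_s[1]
          firsts <- rows$onset_s[seq(1, nrow(rows), by = 2)]
          for (on in firsts) {
            bump(on + lat_of[[sp]], 1)
            bump(on + isi + lat_of[[sp]], ppr_of[[as.character(isi)]])
          }
        }
      }
    }
    keep <- runif(length(cand)) < layer_gain * lambda / rate_max
    spike_times[[i]] <- cand[keep]
  }

  rec <- recording(
    lfp = lfp, fs_lfp = fs, spike_times = spike_times,
    fs_spikes = cf$fs_spikes,
    channel_depths = cf$h_um * seq_len(cf$n_channels),
    contact_spacing_um = cf$h_um,
    age_days = cf$age_days, genotype = cf$genotype, duration = duration
  )
  truth <- structure(
    list(
      planted_bursts = bursts,
      burst_channels = burst_channels,
      granular_channel_range = granular_range,
      granular_center = cf$granular_center,
      evoked_templates = tibble(
        speed_hz = cf$speeds,
        amplitude_mv = cf$speed_amplitudes_mv,
        latency_s = cf$speed_latencies_s
      ),
      prescribed_ppr = tibble(isi_s = cf$isis, ppr = cf$isi_pprs),
      baseline_rate_hz = cf$baseline_rate_hz,
      bad_channels = cf$line_noise_channels,
      noise_spec = list(exponent = cf$pink_exponent, sd_mv = cf$noise_sd_mv),
      baseline_s = cf$baseline_s,
      seed = cf$seed
    ),
    class = "ground_truth"
  )
  list(recording = rec, stimuli = stimuli, truth = truth)
}

#' Generate a multi-group synthetic cohort
#'
#' Builds `n_per_group` subjects for each named configuration, drawing each
#' subject's seed deterministically from the base seed and sampling its age
#' within the group's `age_days` (scalar) or age range (length-2 vector).
#'
#' @param group_configs Named list of [generator_config()] objects (one per
#'   age group / genotype profile); at least 2 groups.
#' @param n_per_group Subjects per group.
#' @param age_ranges Optional named list of `c(lo, hi)` postnatal-day ranges
#'   overriding each config's `age_days`.
#' @param seed Base seed for the cohort.
#' @return List of subjects, each with `recording`, `stimuli`, `truth`,
#'   `group`, `subject_id`.
#' @export
generate_cohort <- function(group_configs, n_per_group, age_ranges = NULL, seed = 1) {
  if (length(group_configs) < 2) abort("need at least 2 groups", class = "lamindev_config_error")
  if (n_per_group < 1) abort("n_per_group must be at least 1", class = "lamindev_config_error")
  out <- list()
  idx <- 0L
  for (g in names(group_configs)) {
    for (j in seq_len(n_per_group)) {
      idx <- idx + 1L
      cf <- group_configs[[g]]
      cf$seed <- (seed * 1000L + idx) %% .Machine$integer.max
      if (!is.null(age_ranges) && !is.null(age_ranges[[g]])) {
        set.seed(cf$seed + 500000L)
        cf$age_days <- sample(seq(age_ranges[[g]][1], age_ranges[[g]][2]), 1)
      }
      sub <- generate_recording(cf)
      sub$group <- g
      sub$subject_id <- sprintf("%s_%02d", g, j)
      out[[idx]] <- sub
    }
  }
  out
}

#' Preset generator profiles for the three developmental windows
#'
#' CP-like (small, slow evoked responses, prominent spindle bursts), pre-AW,
#' and AW-like (large, fast responses, little burst activity) parameter sets,
#' returned as a named list of configs suitable for [generate_cohort()].
#'
#' @param ... Overrides passed to every [generator_config()] (e.g. smaller
#'   `trials_per_block` for test-scale cohorts).
#' @return Named list of three `generator_config`s (`CP`, `preAW`, `AW`).
#' @export
age_group_profiles <- function(...) {
  list(
    CP = generator_config(
      speed_amplitudes_mv = c(0.10, 0.15, 0.22, 0.30, 0.40),
      speed_latencies_s = c(0.110, 0.100, 0.090, 0.080, 0.070),
      burst_rate_per_min = 8, baseline_rate_hz = 1,
      evoked_peak_rate_hz = 20, age_days = 6, ...
    ),
    preAW = generator_config(
      speed_amplitudes_mv = c(0.20, 0.30, 0.45, 0.65, 0.90),
      speed_latencies_s = c(0.080, 0.065, 0.050, 0.040, 0.030),
      burst_rate_per_min = 4, baseline_rate_hz = 2,
      evoked_peak_rate_hz = 60, age_days = 10, ...
    ),
    AW = generator_config(
      speed_amplitudes_mv = c(0.45, 0.65, 0.90, 1.20, 1.55),
      speed_latencies_s = c(0.040, 0.032, 0.026, 0.020, 0.015),
      burst_rate_per_min = 1, baseline_rate_hz = 5,
      evoked_peak_rate_hz = 120, age_days = 14, ...
    )
  )
}

#' Write a ground-truth object as JSON
#'
#' @param truth A `ground_truth` from [generate_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
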
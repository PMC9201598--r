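# Shared fixture builders. All fixtures are generated in code at test time;
# sizes are kept small (short records, few channels) while the scientific
# parameters (band edges, thresholds, prescribed ratios) stay at their
# defaults.

# small but complete recording: baseline + all stimulus kinds
small_config <- function(seed = 1, n_channels = 16, baseline_s = 30,
                         trials_per_block = 3, iti_s = 1.2, ...) {
  generator_config(
    n_channels = n_channels, baseline_s = baseline_s,
    trials_per_block = trials_per_block, iti_s = iti_s, seed = seed, ...
  )
}

# evoked-only recording (short baseline, single-deflection blocks only)
evoked_config <- function(seed = 1, n_channels = 12, baseline_s = 2,
                          trials_per_block = 4, ...) {
  generator_config(
    n_channels = n_channels, baseline_s = baseline_s,
    trials_per_block = trials_per_block, iti_s = 1.2,
    include_paired = FALSE, granular_center = round(n_channels / 2),
    seed = seed, ...
  )
}

# baseline-only recording for spindle-burst work (one token stimulus block)
baseline_config <- function(seed = 1, baseline_s = 60, ...) {
  generator_config(
    n_channels = 8, baseline_s = baseline_s, trials_per_block = 1,
    iti_s = 2, include_paired = FALSE, granular_center = 4,
    speeds = 80, speed_amplitudes_mv = 0.9, speed_latencies_s = 0.03,
    seed = seed, ...
  )
}

# pink-noise trace with Hann-windowed pure-tone bursts planted at known times
make_burst_trace <- function(duration = 60, fs = 1000, onsets = 20,
                             dur = 0.3, freq = 10, amp = 1, noise_sd = 0.1,
                             seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  x <- if (noise_sd > 0) pink_noise(n, sd = noise_sd) else numeric(n)
  k_all <- rep(list(NULL), length(onsets))
  dur <- rep_len(dur, length(onsets))
  freq <- rep_len(freq, length(onsets))
  for (i in seq_along(onsets)) {
    k0 <- round(onsets[i] * fs) + 1
    k1 <- k0 + round(dur[i] * fs) - 1
    tt <- (seq(k0, k1) - k0) / fs
    x[k0:k1] <- x[k0:k1] +
      amp * 0.5 * (1 - cos(2 * pi * tt / dur[i])) * sin(2 * pi * freq[i] * tt)
  }
  x
}

# independent brute-force spindle detector used as the oracle: same published
# recipe (5-35 Hz Butterworth, envelope, mean + 2 SD) but written from
# scratch with its own envelope and run/trough scanning code
oracle_detect <- function(x, fs, min_duration = 0.1, min_troughs = 3,
                          merge_gap = 0.05) {
  bf <- signal::butter(4, c(5, 35) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, x - mean(x))
  n <- length(filt)
  X <- stats::fft(filt)
  w <- c(1, rep(2, ceiling(n / 2) - 1), rep(0, floor(n / 2)))
  if (n %% 2 == 0) w[n / 2 + 1] <- 1
  env <- Mod(stats::fft(X * w, inverse = TRUE) / n)
  thr <- mean(env) + 2 * stats::sd(env)
  edge <- stats::median(env)
  above <- which(env > thr)
  if (!length(above)) {
    return(data.frame(onset = numeric(0), duration = numeric(0), troughs = integer(0)))
  }
  brk <- which(diff(above) > 1)
  starts <- above[c(1, brk + 1)]
  ends <- above[c(brk, length(above))]
  # merge flicker, then screen the putative events on duration and troughs
  i <- 1
  while (i < length(starts)) {
    if ((starts[i + 1] - ends[i] - 1) / fs < merge_gap) {
      ends[i] <- ends[i + 1]
      starts <- starts[-(i + 1)]
      ends <- ends[-(i + 1)]
    } else {
      i <- i + 1
    }
  }
  n_troughs <- function(a, b) {
    seg <- filt[a:b]
    if (length(seg) < 3) return(0L)
    j <- seq(2, length(seg) - 1)
    sum(seg[j] < 0 & seg[j] < seg[j - 1] & seg[j] < seg[j + 1])
  }
  ok <- mapply(function(a, b) (b - a + 1) / fs >= min_duration &&
    n_troughs(a, b) >= min_troughs, starts, ends)
  starts <- starts[ok]
  ends <- ends[ok]
  if (!length(starts)) {
    return(data.frame(onset = numeric(0), duration = numeric(0), troughs = integer(0)))
  }
  # extend to the edge threshold, then to the smoothed-envelope local minimum
  k <- round(0.05 * fs)
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  pad <- c(rep(env[1], half), env, rep(env[length(env)], half))
  env_s <- as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2))[(half + 1):(half + length(env))]
  for (i in seq_along(starts)) {
    while (starts[i] > 1 && env[starts[i] - 1] > edge) starts[i] <- starts[i] - 1
    while (ends[i] < length(env) && env[ends[i] + 1] > edge) ends[i] <- ends[i] + 1
    while (starts[i] > 1 && env_s[starts[i] - 1] < env_s[starts[i]]) starts[i] <- starts[i] - 1
    while (ends[i] < length(env) && env_s[ends[i] + 1] < env_s[ends[i]]) ends[i] <- ends[i] + 1
  }
  uniq <- !duplicated(paste(starts, ends))
  starts <- starts[uniq]
  ends <- ends[uniq]
  i <- 1
  while (i < length(starts)) {
    if (starts[i + 1] <= ends[i]) {
      ends[i] <- max(ends[i], ends[i + 1])
      starts <- starts[-(i + 1)]
      ends <- ends[-(i + 1)]
    } else {
      i <- i + 1
    }
  }
  # reported troughs are gated on the envelope clearing the noise floor
  n_troughs_gated <- function(a, b) {
    seg <- filt[a:b]
    es <- env[a:b]
    j <- seq(2, length(seg) - 1)
    sum(seg[j] < 0 & seg[j] < seg[j - 1] & seg[j] < seg[j + 1] &
      es[j] > edge & seg[j] < -edge)
  }
  data.frame(
    onset = (starts - 1) / fs,
    duration = (ends - starts + 1) / fs,
    troughs = mapply(n_troughs_gated, starts, ends)
  )
}

# build stage-ready subject summaries (reference-speed evoked LFP + PSTH on
# the granular sink-centre channel) straight from generator output
subject_summaries <- function(cohort, window = c(-0.1, 0.5)) {
  lapply(cohort, function(s) {
    ons <- s$stimuli$onset_s[s$stimuli$kind == "single"]
    centre <- s$truth$granular_center
    g_ch <- s$truth$granular_channel_range
    spk <- sort(unlist(s$recording$spike_times[g_ch], use.names = FALSE))
    list(
      lfp = average_evoked(s$recording$lfp[centre, ], s$recording$fs_lfp, ons,
        window = window
      ),
      mua = compute_psth(spk, ons, window = window),
      subject_id = s$subject_id %||% "s",
      age_days = s$recording$age_days,
      group = s$group
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
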
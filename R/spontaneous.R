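#' Area-normalized Welch spectrum with canonical band powers
#'
#' Welch PSD on 4 s non-overlapping segments, normalized so the trapezoidal
#' integral over the computed frequency range equals 1; band powers are the
#' mean normalized density within alpha-theta (5-15 Hz), beta (15-30 Hz) and
#' gamma (30-50 Hz).
#'
#' @param x Single-channel LFP, millivolts.
#' @param fs Sampling rate, Hz.
#' @param seg_sec Welch segment length, s (segments do not overlap).
#' @param bands Named list of `c(lo, hi)` band edges, Hz.
#' @param fmax Upper edge of the computed range; defaults to Nyquist.
#' @return A `spectral_summary`: list with `psd` (tibble `freq`, `density`)
#'   and `band_powers` (tibble `band`, `lo_hz`, `hi_hz`, `power`).
#' @export
welch_band_power <- function(x, fs, seg_sec = 4,
                             bands = list(
                               alpha_theta = c(5, 15),
                               beta = c(15, 30),
                               gamma = c(30, 50)
                             ),
                             fmax = fs / 2) {
  psd <- welch_psd(x, fs, seg_sec = seg_sec)
  psd <- psd[psd$freq <= fmax, ]
  area <- trapz(psd$freq, psd$power)
  if (area <= 0) abort("zero-power signal cannot be normalized", class = "lamindev_numeric_error")
  density <- psd$power / area
  bp <- purrr::imap_dfr(bands, function(b, nm) {
    sel <- psd$freq >= b[1] & psd$freq <= b[2]
    tibble(band = nm, lo_hz = b[1], hi_hz = b[2], power = mean(density[sel]))
  })
  structure(
    list(psd = tibble(freq = psd$freq, density = density), band_powers = bp),
    class = "spectral_summary"
  )
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary>\n")
  print(x$band_powers)
  invisible(x)
}

#' Detect spindle bursts with a Hilbert-envelope threshold
#'
#' The signal is band-passed 5-35 Hz with a 4th-order Butterworth filter
#' applied forward and backward (zero phase, so event onsets are not skewed;
#' the effective magnitude order doubles). The analytic-signal envelope is
#' thresholded at `mean + threshold_sd * SD` of the envelope over the whole
#' record; maximal supra-threshold intervals are putative event cores.
#' Because an oscillatory burst waxes and wanes, each core is then extended
#' outward to where the envelope falls below a lower edge threshold (a
#' robust, MAD-based level that tracks the noise floor) and on to the local
#' minimum of a lightly smoothed envelope — the usual two-threshold scheme
#' plus onset refinement, which keeps event boundaries from lagging up the
#' rising flank. Extended intervals separated by
#' less than `merge_gap` are merged, and events shorter than `min_duration`
#' or containing fewer than `min_troughs` troughs are discarded. Troughs are
#' strict local minima of the filtered trace with negative value inside the
#' event (plateaus count once, at their first sample). Intra-event frequency
#' is troughs / duration.
#'
#' @param x Single-channel LFP, millivolts.
#' @param fs Sampling rate, Hz (>= 100).
#' @param band Pass band, Hz.
#' @param order Butterworth order (per pass).
#' @param threshold_sd Core detection threshold in SDs above the mean
#'   envelope.
#' @param edge_sd Lower edge threshold to which event boundaries are
#'   extended, in robust-SD units (MAD-based) above the median envelope; the
#'   edge tracks the noise floor, so robust statistics keep it from being
#'   inflated by the events themselves.
#' @param refine_w Width (s) of the boxcar used to smooth the envelope for
#'   the final boundary refinement to its local minimum; 0 disables.
#' @param threshold_on `"envelope"` (default) thresholds the envelope at its
#'   own mean + SD; `"raw"` uses mean + SD of the filtered trace instead.
#' @param min_duration Minimum event duration, s.
#' @param min_troughs Minimum trough count.
#' @param merge_gap Putative events closer than this gap (s) are merged
#'   before screening.
#' @return A `spindle_events` tibble: `onset_s`, `duration_s`, `trough_count`,
#'   `intra_freq_hz`, `peak_envelope_mv`; attributes `fs` and `total_duration`.
#' @export
detect_spindle_bursts <- function(x, fs, band = c(5, 35), order = 4,
                                  threshold_sd = 2, edge_sd = 0,
                                  refine_w = 0.05,
                                  threshold_on = c("envelope", "raw"),
                                  min_duration = 0.1, min_troughs = 3,
                                  merge_gap = 0.05) {
  threshold_on <- match.arg(threshold_on)
  if (any(!is.finite(x))) abort("non-finite samples", class = "lamindev_numeric_error")
  if (fs < 100) abort("fs must be at least 100 Hz", class = "lamindev_format_error")
  x <- x - mean(x) # make detection exactly invariant to a DC offset
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, x)
  env <- Mod(analytic_signal(filt))
  if (threshold_on == "envelope") {
    thr <- mean(env) + threshold_sd * sd(env)
  } else {
    thr <- mean(filt) + threshold_sd * sd(filt)
  }
  # the edge level tracks the noise floor, so robust statistics: the events
  # themselves would otherwise inflate a mean/SD-based edge
  edge <- median(env) + edge_sd * stats::mad(env)
  above <- env > thr
  runs <- run_bounds(above)
  # merge supra-threshold flicker before screening
  if (nrow(runs) > 1 && merge_gap > 0) {
    gap <- (runs$start[-1] - runs$end[-nrow(runs)] - 1) / fs
    grp <- cumsum(c(1, gap >= merge_gap))
    runs <- tibble(
      start = as.numeric(tapply(runs$start, grp, min)),
      end = as.numeric(tapply(runs$end, grp, max))
    )
  }
  # duration and trough screening applies to the putative (supra-threshold)
  # event itself, so spurious short threshold crossings never survive
  if (nrow(runs)) {
    core_ok <- vapply(seq_len(nrow(runs)), function(i) {
      (runs$end[i] - runs$start[i] + 1) / fs >= min_duration &&
        count_troughs(filt[runs$start[i]:runs$end[i]]) >= min_troughs
    }, logical(1))
    runs <- runs[core_ok, , drop = FALSE]
  }
  # extend surviving events outward to the noise-floor edge threshold and on
  # to the local minimum of the smoothed envelope: the reported onset and
  # duration then cover the full flank, not just the supra-threshold crest
  if (nrow(runs)) {
    below_edge <- env <= edge
    runs$start <- vapply(runs$start, function(s) {
      j <- which(below_edge[seq_len(s)])
      if (length(j)) max(j) + 1 else 1
    }, double(1))
    runs$end <- vapply(runs$end, function(e) {
      j <- which(below_edge[e:length(env)])
      if (length(j)) e + min(j) - 2 else length(env)
    }, double(1))
    if (refine_w > 0) {
      k <- round(refine_w * fs)
      if (k %% 2 == 0) k <- k + 1
      half <- (k - 1) / 2
      ep <- c(rep(env[1], half), env, rep(env[length(env)], half))
      cs <- c(0, cumsum(ep))
      env_s <- (cs[(k + 1):(length(env) + k)] - cs[seq_along(env)]) / k
      for (i in seq_len(nrow(runs))) {
        s <- runs$start[i]
        while (s > 1 && env_s[s - 1] < env_s[s]) s <- s - 1
        runs$start[i] <- s
        e <- runs$end[i]
        while (e < length(env) && env_s[e + 1] < env_s[e]) e <- e + 1
        runs$end[i] <- e
      }
    }
    # events extending into the same envelope trough collapse to one
    runs <- dplyr::distinct(runs)
    if (nrow(runs) > 1) {
      i <- 1
      while (i < nrow(runs)) {
        if (runs$start[i + 1] <= runs$end[i]) {
          runs$end[i] <- max(runs$end[i], runs$end[i + 1])
          runs <- runs[-(i + 1), ]
        } else {
          i <- i + 1
        }
      }
    }
  }
  events <- purrr::pmap_dfr(runs, function(start, end) {
    seg <- filt[start:end]
    troughs <- count_troughs(seg, env[start:end], gate = edge)
    dur <- (end - start + 1) / fs
    tibble(
      onset_s = (start - 1) / fs,
      duration_s = dur,
      trough_count = troughs,
      intra_freq_hz = troughs / dur,
      peak_envelope_mv = max(env[start:end])
    )
  })
  if (!nrow(events)) {
    events <- tibble(
      onset_s = numeric(0), duration_s = numeric(0), trough_count = integer(0),
      intra_freq_hz = numeric(0), peak_envelope_mv = numeric(0)
    )
  }
  structure(events,
    class = c("spindle_events", class(tibble())),
    fs = fs, total_duration = length(x) / fs
  )
}

# start/end sample indices of TRUE runs
run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

# strict local minima below zero; a plateau minimum counts at its first
# sample. When an envelope segment and gate level are supplied, a trough only
# counts where the envelope clears the gate and the trough itself dips below
# -gate, so shallow noise dips in the low-amplitude fringe of an event are
# not mistaken for oscillation cycles.
count_troughs <- function(seg, env_seg = NULL, gate = -Inf) {
  n <- length(seg)
  if (n < 3) {
    return(0L)
  }
  count <- 0L
  i <- 2L
  while (i < n) {
    if (seg[i] < seg[i - 1] && seg[i] < 0) {
      j <- i
      while (j < n && seg[j + 1] == seg[j]) j <- j + 1
      if (j < n && seg[j + 1] > seg[j] &&
        (is.null(env_seg) || (env_seg[i] > gate && seg[i] < -gate))) {
        count <- count + 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Summary statistics of detected spindle bursts
#'
#' @param events A `spindle_events` tibble from [detect_spindle_bursts()].
#' @param total_duration Length of the analyzed record, s.
#' @return One-row tibble: `n_events`, `rate_per_min`, `mean_duration_s`,
#'   `mean_intra_freq_hz`, `pct_time_in_events`. With no events the rate and
#'   time fraction are 0 and the means are `NA` (undefined).
#' @export
sb_stats <- function(events, total_duration) {
  if (total_duration <= 0) abort("total_duration must be positive", class = "lamindev_validation_error")
  if (nrow(events) && any(events$onset_s + events$duration_s > total_duration + 1e-9)) {
    abort("event extends past total_duration", class = "lamindev_consistency_error")
  }
  tibble(
    n_events = nrow(events),
    rate_per_min = 60 * nrow(events) / total_duration,
    mean_duration_s = if (nrow(events)) mean(events$duration_s) else NA_real_,
    mean_intra_freq_hz = if (nrow(events)) mean(events$intra_freq_hz) else NA_real_,
    pct_time_in_events = 100 * sum(events$duration_s) / total_duration
  )
}

#' Event-aligned average wavelet spectrogram
#'
#' Computes the complex-Morlet CWT magnitude of a fixed-length segment
#' starting at each event onset and averages across events. Events whose
#' window does not fit inside the record are skipped with a warning.
#'
#' @param x Single-channel LFP.
#' @param fs Sampling rate, Hz.
#' @param events `spindle_events` tibble (only `onset_s` is used).
#' @param window Segment length from event onset, s.
#' @param freqs Analysis frequencies, Hz (default 48 log-spaced, 5-50 Hz).
#' @return An `event_spectrogram`: list with `time` (s from onset), `freqs`,
#'   `magnitude` (freq x time average) and `n_events` averaged.
#' @export
event_spectrogram <- function(x, fs, events, window = 1,
                              freqs = exp(seq(log(5), log(50), length.out = 48))) {
  if (nrow(events) == 0) abort("no events to average", class = "lamindev_empty_error")
  nwin <- round(window * fs)
  acc <- NULL
  used <- 0L
  for (on in events$onset_s) {
    i0 <- round(on * fs) + 1
    if (i0 < 1 || i0 + nwin - 1 > length(x)) {
      warn(sprintf("event at %.3f s does not fit the %g s window; skipped", on, window))
      next
    }
    cw <- morlet_cwt(x[i0:(i0 + nwin - 1)], fs, freqs = freqs)
    acc <- if (is.null(acc)) cw$magnitude else acc + cw$magnitude
    used <- used + 1L
  }
  if (used == 0) abort("no event window fits the record", class = "lamindev_empty_error")
  structure(
    list(
      time = (seq_len(nwin) - 1) / fs, freqs = freqs,
      magnitude = acc / used, n_events = used
    ),
    class = "event_spectrogram"
  )
}

#' Baseline multi-unit firing rate
#'
#' Spike counts in consecutive non-overlapping windows (default 500 ms) are
#' converted to rates and averaged into a gross mean rate. With windows tiling
#' the record exactly this equals total count / duration.
#'
#' @param spike_times Spike times, s.
#' @param total_duration Record length, s (>= 1).
#' @param window Averaging window, s.
#' @return Mean firing rate, Hz.
#' @export
baseline_firing_rate <- function(spike_times, total_duration, window = 0.5) {
  if (total_duration < 1) abort("need at least 1 s", class = "lamindev_length_error")
  if (length(spike_times) && min(spike_times) < 0) {
    abort("negative spike times", class = "lamindev_validation_error")
  }
  n_win <- floor(total_duration / window)
  sp <- spike_times[spike_times < n_win * window]
  counts <- tabulate(floor(sp / window) + 1, nbins = n_win)
  mean(counts / window)
}
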
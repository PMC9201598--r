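#' Trial-averaged sensory-evoked LFP
#'
#' Aligns the signal on each stimulus onset, subtracts the per-trial mean of
#' the 100 ms pre-stimulus baseline, and averages across trials.
#'
#' @param x Single-channel (typically layer-averaged) LFP, millivolts.
#' @param fs Sampling rate, Hz.
#' @param onsets Stimulus onset times, s; trials whose window falls outside
#'   the record are dropped.
#' @param window Trial window relative to onset, s.
#' @param baseline Pre-stimulus baseline length, s.
#' @return An `evoked_response` with `time` (s, relative to onset), `mean`
#'   (mV), `n_trials`, `fs`, `kind = "lfp"`.
#' @export
average_evoked <- function(x, fs, onsets, window = c(-0.1, 0.5), baseline = 0.1) {
  i0 <- round(window[1] * fs)
  i1 <- round(window[2] * fs)
  keep <- round(onsets * fs) + 1 + i0 >= 1 & round(onsets * fs) + 1 + i1 <= length(x)
  onsets <- onsets[keep]
  if (!length(onsets)) abort("no complete trials", class = "lamindev_empty_error")
  tvec <- seq(i0, i1) / fs
  base_sel <- tvec >= -baseline & tvec < 0
  acc <- numeric(length(tvec))
  for (on in onsets) {
    c0 <- round(on * fs) + 1
    trial <- x[(c0 + i0):(c0 + i1)]
    acc <- acc + (trial - mean(trial[base_sel]))
  }
  structure(
    list(time = tvec, mean = acc / length(onsets), n_trials = length(onsets),
         fs = fs, kind = "lfp"),
    class = "evoked_response"
  )
}

#' Peri-stimulus time histogram of multi-unit activity
#'
#' Spike counts in 1 ms bins summed across trials, converted to a per-trial
#' rate (counts / (n_trials x bin)), smoothed with a zero-padded 5 ms boxcar
#' (which conserves the total count), and baseline-corrected by subtracting
#' the mean rate of the 100 ms pre-stimulus bins. Smoothing precedes the
#' baseline subtraction.
#'
#' @param spike_times Pooled spike times, s (all channels of a layer).
#' @param onsets Stimulus onset times, s.
#' @param fs Nominal rate defining achievable bin edges (not used beyond
#'   validation); may be `NULL`.
#' @param window Trial window relative to onset, s.
#' @param bin Bin width, s.
#' @param smooth Boxcar width, s; must be an odd multiple of `bin` so the
#'   kernel can be centred.
#' @param baseline Pre-stimulus baseline length, s.
#' @return An `evoked_response` with `time` (bin centres, s), `mean` (rate,
#'   spikes/s per trial, smoothed and baseline-subtracted), `counts` (raw
#'   summed counts per bin, pre-smoothing), `n_trials`, `kind = "mua"`.
#' @export
compute_psth <- function(spike_times, onsets, fs = NULL, window = c(-0.1, 0.5),
                         bin = 0.001, smooth = 0.005, baseline = 0.1) {
  k <- smooth / bin
  if (abs(k - round(k)) > 1e-9 || round(k) %% 2 != 1) {
    abort("smooth must be an odd multiple of bin (kernel centring undefined otherwise)",
      class = "lamindev_config_error"
    )
  }
  n_bins <- round((window[2] - window[1]) / bin)
  edges <- window[1] + bin * seq(0, n_bins)
  counts <- numeric(n_bins)
  n_trials <- length(onsets)
  if (!n_trials) abort("no trials", class = "lamindev_empty_error")
  for (on in onsets) {
    rel <- spike_times - on
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      counts <- counts + tabulate(floor((rel - window[1]) / bin) + 1, nbins = n_bins)
    }
  }
  rate <- counts / (n_trials * bin)
  smoothed <- boxcar_smooth(rate, round(k))
  centres <- edges[-1] - bin / 2
  base_sel <- centres > -baseline & centres < 0
  corrected <- smoothed - mean(smoothed[base_sel])
  structure(
    list(time = centres, mean = corrected, counts = counts,
         rate_smoothed = smoothed, n_trials = n_trials, fs = 1 / bin,
         kind = "mua"),
    class = "evoked_response"
  )
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf(
    "<evoked_response:%s> %d trials | window [%.3f, %.3f] s | %d samples\n",
    x$kind, x$n_trials, min(x$time), max(x$time), length(x$time)
  ))
  invisible(x)
}

#' Peak amplitude and latency of an evoked response
#'
#' For LFP responses the peak is the most negative deflection in the search
#' window and the amplitude its magnitude; for MUA the peak is the maximum
#' rate. Latency is measured from stimulus onset to the extremum; equal
#' extrema resolve to the earliest sample. A flat response is flagged
#' degenerate with undefined latency.
#'
#' @param resp An `evoked_response` (or list with `time` and `mean`).
#' @param search_window Post-onset search window, s.
#' @param polarity `"negative"` (LFP) or `"positive"` (MUA); default chosen
#'   from `resp$kind`.
#' @return One-row tibble: `amplitude`, `latency_ms`, `degenerate`.
#' @export
peak_metrics <- function(resp, search_window = c(0, 0.1), polarity = NULL) {
  polarity <- polarity %||% if (identical(resp$kind, "mua")) "positive" else "negative"
  sel <- resp$time >= search_window[1] & resp$time <= search_window[2]
  if (!any(sel)) abort("search window outside response window", class = "lamindev_window_error")
  y <- resp$mean[sel]
  t_sub <- resp$time[sel]
  if (max(y) == min(y)) {
    return(tibble(amplitude = 0, latency_ms = NA_real_, degenerate = TRUE))
  }
  idx <- if (polarity == "negative") which.min(y) else which.max(y)
  tibble(
    amplitude = abs(y[idx]),
    latency_ms = 1000 * t_sub[idx],
    degenerate = FALSE
  )
}

#' Paired-pulse ratio
#'
#' Measures a peak independently after each of the two deflection onsets
#' (each relative to its own pre-onset baseline; the second baseline is
#' shortened to `min(baseline, 0.4 * ISI)` so that at short intervals it
#' stays clear of the first response's decay) and returns second / first. The second response is flagged
#' a failure when its peak does not exceed `failure_threshold` times the
#' standard deviation of the first pre-stimulus baseline.
#'
#' @param x Trial-averaged signal vector (LFP mV or MUA rate), time base
#'   starting at sample 1 = 0 s.
#' @param fs Sampling rate, Hz.
#' @param onset1,onset2 The two deflection onsets, s (`onset2 - onset1` is the
#'   ISI).
#' @param search_window Peak search window after each onset, s; the second
#'   window is additionally truncated at the ISI so it cannot overlap a
#'   following stimulus.
#' @param baseline Baseline length, s.
#' @param polarity `"negative"` (LFP) or `"positive"` (MUA).
#' @param failure_threshold Failure criterion in baseline-noise SDs.
#' @return One-row tibble: `ppr`, `first_peak`, `second_peak`, `isi_s`,
#'   `failure`.
#' @export
paired_pulse_ratio <- function(x, fs, onset1, onset2, search_window = 0.1,
                               baseline = 0.1, polarity = "negative",
                               failure_threshold = 2) {
  isi <- onset2 - onset1
  if (isi <= 0) abort("onset2 must follow onset1", class = "lamindev_validation_error")
  peak_after <- function(onset, base_len, win_len) {
    b0 <- max(1, round((onset - base_len) * fs) + 1)
    b1 <- round(onset * fs)
    seg_base <- x[b0:b1]
    i0 <- round(onset * fs) + 1
    i1 <- min(length(x), round((onset + win_len) * fs))
    seg <- x[i0:i1] - mean(seg_base)
    amp <- if (polarity == "negative") max(-seg) else max(seg)
    # an absent response never deflects past its own baseline: clamp at 0
    list(amp = max(0, amp), noise_sd = sd(seg_base))
  }
  first <- peak_after(onset1, baseline, min(search_window, isi))
  second <- peak_after(onset2, min(baseline, 0.4 * isi), min(search_window, isi))
  if (first$amp < failure_threshold * first$noise_sd) {
    abort("first response below the noise floor; PPR undefined",
      class = "lamindev_undefined_ppr_error"
    )
  }
  tibble(
    ppr = second$amp / first$amp,
    first_peak = first$amp,
    second_peak = second$amp,
    isi_s = isi,
    failure = second$amp < failure_threshold * first$noise_sd
  )
}

#' Descriptive aggregation of per-subject evoked metrics
#'
#' Collapses a tidy metric table to per-condition summaries. Each subject is
#' first reduced to its own mean, then the group mean, SEM and N (number of
#' subjects) are reported per (genotype, age window, layer, condition) cell —
#' N counts subjects, not trials. Cells losing subjects relative to the fullest
#' cell are reported with their reduced N and mentioned in a message.
#'
#' @param metrics Tibble with columns `subject_id`, `genotype`, `age_window`,
#'   `layer`, `condition` and one numeric `value` column.
#' @param value Name of the numeric column to aggregate (string).
#' @return Tibble with `genotype`, `age_window`, `layer`, `condition`, `n`,
#'   `mean`, `sem`.
#' @export
condition_aggregate <- function(metrics, value = "amplitude") {
  need <- c("subject_id", "genotype", "age_window", "layer", "condition", value)
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    abort(paste0("metrics missing column(s): ", paste(miss, collapse = ", ")),
      class = "lamindev_grouping_error"
    )
  }
  per_subject <- metrics |>
    group_by(.data$genotype, .data$age_window, .data$layer, .data$condition,
      .data$subject_id) |>
    summarise(value = mean(.data[[value]]), .groups = "drop")
  out <- per_subject |>
    group_by(.data$genotype, .data$age_window, .data$layer, .data$condition) |>
    summarise(
      n = n_distinct(.data$subject_id),
      mean = mean(.data$value),
      sem = if (n_distinct(.data$subject_id) > 1) {
        sd(.data$value) / sqrt(n_distinct(.data$subject_id))
      } else {
        0
      },
      .groups = "drop"
    )
  if (length(unique(out$n)) > 1) {
    inform(sprintf(
      "unequal subject counts across cells (N ranges %d-%d)",
      min(out$n), max(out$n)
    ))
  }
  out
}
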
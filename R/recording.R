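#' Construct a laminar recording object
#'
#' A `recording` bundles the multi-channel LFP matrix, per-channel spike-time
#' lists produced upstream by a spike sorter, the probe geometry and subject
#' metadata. Depths increase with channel index (channel 1 is most
#' superficial) and must be equally spaced by `contact_spacing_um`.
#'
#' @param lfp Channels x samples numeric matrix, millivolts.
#' @param fs_lfp LFP sampling rate, Hz (must exceed 100 Hz so the 50 Hz QC is
#'   defined).
#' @param spike_times List (one element per channel) of numeric spike times in
#'   seconds.
#' @param fs_spikes Sampling rate of the acquisition clock the spike times were
#'   derived from, Hz (metadata only).
#' @param channel_depths Depths in micrometers, strictly increasing.
#' @param contact_spacing_um Vertical contact spacing h, micrometers.
#' @param age_days Subject age in postnatal days.
#' @param genotype Free-text genotype / group label.
#' @param duration Recording duration, seconds.
#' @return An object of class `recording`.
#' @export
recording <- function(lfp, fs_lfp, spike_times, fs_spikes, channel_depths,
                      contact_spacing_um, age_days, genotype = "WT",
                      duration = ncol(lfp) / fs_lfp) {
  rec <- structure(
    list(
      lfp = lfp, fs_lfp = fs_lfp, spike_times = spike_times,
      fs_spikes = fs_spikes, channel_depths = channel_depths,
      contact_spacing_um = contact_spacing_um,
      age_days = age_days, genotype = genotype, duration = duration
    ),
    class = "recording"
  )
  validate_recording(rec)
}

#' Validate a recording's structural invariants
#'
#' @param rec A `recording`.
#' @return `rec`, invisibly unchanged, or an error describing the violation.
#' @export
validate_recording <- function(rec) {
  if (!is.matrix(rec$lfp) || !is.numeric(rec$lfp)) {
    abort("lfp must be a numeric channels x samples matrix", class = "lamindev_format_error")
  }
  n_ch <- nrow(rec$lfp)
  if (n_ch < 3) abort("need at least 3 channels", class = "lamindev_format_error")
  if (rec$fs_lfp <= 100) {
    abort("fs_lfp must exceed 100 Hz (twice the 50 Hz line frequency)",
      class = "lamindev_format_error"
    )
  }
  if (length(rec$channel_depths) != n_ch) {
    abort("channel_depths length must match channel count", class = "lamindev_format_error")
  }
  dd <- diff(rec$channel_depths)
  if (any(dd <= 0)) {
    abort("channel_depths must be strictly increasing", class = "lamindev_geometry_error")
  }
  if (any(abs(dd - rec$contact_spacing_um) > 0.01 * rec$contact_spacing_um)) {
    abort("depth spacing non-uniform beyond 1% of contact_spacing_um",
      class = "lamindev_geometry_error"
    )
  }
  if (length(rec$spike_times) != n_ch) {
    abort("spike_times must have one element per channel", class = "lamindev_format_error")
  }
  all_sp <- unlist(rec$spike_times, use.names = FALSE)
  if (length(all_sp) && (min(all_sp) < 0 || max(all_sp) > rec$duration)) {
    abort("spike times must lie within [0, duration]", class = "lamindev_validation_error")
  }
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %.1f s @ %g Hz | h = %g um | P%d %s | %d spikes\n",
    nrow(x$lfp), x$duration, x$fs_lfp, x$contact_spacing_um,
    x$age_days, x$genotype, length(unlist(x$spike_times))
  ))
  invisible(x)
}

#' Validate a stimulus event table
#'
#' Checks the deflection table contract: strictly increasing onsets, single
#' condition label per block, and paired-pulse rows carrying an ISI.
#'
#' @param stim Tibble with columns `onset_s`, `kind` ("single" or "paired"),
#'   `speed_hz`, `isi_s`, `block`.
#' @return `stim` as a tibble, invisibly, or an error.
#' @export
validate_stimulus_table <- function(stim) {
  need <- c("onset_s", "kind", "speed_hz", "isi_s", "block")
  miss <- setdiff(need, names(stim))
  if (length(miss)) {
    abort(paste0("stimulus table missing column(s): ", paste(miss, collapse = ", ")),
      class = "lamindev_format_error"
    )
  }
  if (is.unsorted(stim$onset_s, strictly = TRUE)) {
    abort("stimulus onsets must be strictly increasing", class = "lamindev_validation_error")
  }
  for (b in unique(stim$block)) {
    rows <- stim[stim$block == b, ]
    if (length(unique(rows$kind)) != 1 ||
      length(unique(rows$speed_hz)) != 1 ||
      length(unique(stats::na.omit(rows$isi_s))) > 1) {
      abort(sprintf("block %s mixes condition labels", b), class = "lamindev_validation_error")
    }
  }
  invisible(as_tibble(stim))
}
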
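#' Three-point Hamming smoothing of a depth profile
#'
#' Replaces each interior value by `0.23 * x[i-1] + 0.54 * x[i] + 0.23 *
#' x[i+1]`; end channels are handled by duplicating the boundary value, the
#' same padding convention used by the Vaknin boundary correction. Accepts a
#' vector (one depth profile) or a channels x samples matrix (smoothed
#' column-wise along depth).
#'
#' @param x Numeric vector (length >= 3) or matrix (>= 3 rows).
#' @return Smoothed object of the same shape.
#' @export
hamming_smooth <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 3) abort("need at least 3 channels", class = "lamindev_size_error")
    padded <- rbind(x[1, , drop = FALSE], x, x[nrow(x), , drop = FALSE])
    return(0.23 * padded[1:nrow(x), , drop = FALSE] +
      0.54 * padded[2:(nrow(x) + 1), , drop = FALSE] +
      0.23 * padded[3:(nrow(x) + 2), , drop = FALSE])
  }
  if (length(x) < 3) abort("need at least 3 channels", class = "lamindev_size_error")
  padded <- c(x[1], x, x[length(x)])
  0.23 * padded[1:length(x)] + 0.54 * padded[2:(length(x) + 1)] +
    0.23 * padded[3:(length(x) + 2)]
}

#' Estimate current-source density across the laminar probe
#'
#' Second spatial difference of the potential profile, sinks negative:
#' `C(z) = -(phi(z+h) - 2 phi(z) + phi(z-h)) / h^2`. With `vaknin = TRUE` the
#' profile is padded by duplicating the topmost and bottommost contacts so the
#' CSD is defined at the boundary channels and the output keeps the input
#' channel count. Optional pre-processing: averaging of vertically adjacent
#' contact pairs (collapsing a staggered two-column probe to one depth column;
#' effective spacing doubles) and three-point Hamming smoothing of each depth
#' profile. Order of operations: pair-average, Vaknin pad, Hamming, difference.
#' Extracellular conductivity is not modeled, so units are mV/um^2 up to that
#' constant; only relative sink structure is interpreted downstream.
#'
#' @param lfp Channels x samples numeric matrix (a vector is treated as a
#'   single-sample profile), millivolts.
#' @param h Vertical contact spacing, micrometers.
#' @param time Optional time axis (s, relative to stimulus onset) stored on
#'   the result.
#' @param pair_average Average adjacent contact pairs before differencing.
#' @param smooth Apply [hamming_smooth()] to each depth profile.
#' @param vaknin Duplicate boundary contacts so output channel count equals
#'   input channel count.
#' @return A `csd_map`: list with `csd` (channels x samples, sinks negative),
#'   `time`, `depth_index` (row indices into the differenced profile), `h`,
#'   and `sinks_negative = TRUE`.
#' @export
estimate_csd <- function(lfp, h, time = NULL, pair_average = FALSE,
                         smooth = FALSE, vaknin = TRUE) {
  if (is.vector(lfp)) lfp <- matrix(lfp, ncol = 1)
  if (any(!is.finite(lfp))) abort("non-finite LFP input", class = "lamindev_numeric_error")
  if (h <= 0) abort("contact spacing h must be positive", class = "lamindev_geometry_error")
  phi <- lfp
  if (pair_average) {
    n_pair <- floor(nrow(phi) / 2)
    phi <- (phi[2 * seq_len(n_pair) - 1, , drop = FALSE] +
      phi[2 * seq_len(n_pair), , drop = FALSE]) / 2
    h <- 2 * h
  }
  if (nrow(phi) < 3) abort("need at least 3 channels", class = "lamindev_size_error")
  if (vaknin) {
    phi <- rbind(phi[1, , drop = FALSE], phi, phi[nrow(phi), , drop = FALSE])
  }
  if (smooth) phi <- hamming_smooth(phi)
  n <- nrow(phi)
  csd <- -(phi[3:n, , drop = FALSE] - 2 * phi[2:(n - 1), , drop = FALSE] +
    phi[1:(n - 2), , drop = FALSE]) / h^2
  structure(
    list(
      csd = csd,
      time = time %||% (seq_len(ncol(csd)) - 1),
      # channel indices (post pair-averaging) each CSD row refers to
      depth_index = if (vaknin) seq_len(nrow(csd)) else 1 + seq_len(nrow(csd)),
      h = h,
      pair_average = pair_average,
      sinks_negative = TRUE
    ),
    class = "csd_map"
  )
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf(
    "<csd_map> %d channels x %d samples | h = %g um | sinks negative\n",
    nrow(x$csd), ncol(x$csd), x$h
  ))
  invisible(x)
}

#' Assign cortical layer groups from the earliest large CSD sink
#'
#' On a stimulus-aligned averaged CSD map, the channel carrying the
#' shortest-latency, large-amplitude sink is classified as granular; the
#' granular range extends to contiguous neighbors whose sinks also exceed the
#' amplitude criterion with peak latency within `latency_tol` of the seed.
#' Channels above the granular range are supragranular, channels below are
#' infragranular.
#'
#' @param csd_map A `csd_map` whose `time` axis is seconds relative to
#'   stimulus onset.
#' @param search_window Post-stimulus window (s) searched for sinks.
#' @param amplitude_fraction A channel qualifies when its sink magnitude
#'   exceeds this fraction of the largest sink magnitude on the map.
#' @param latency_tol Latency tolerance (s) for extending the granular range
#'   to contiguous qualifying neighbors.
#' @return A `layer_assignment`: granular/supragranular/infragranular channel
#'   index vectors, `sink_channel`, `sink_latency_ms`, `sink_amplitude`.
#' @export
assign_layers <- function(csd_map, search_window = c(0, 0.1),
                          amplitude_fraction = 0.5, latency_tol = 0.01) {
  stopifnot(inherits(csd_map, "csd_map"))
  sel <- csd_map$time >= search_window[1] & csd_map$time <= search_window[2]
  if (!any(sel)) abort("search window outside the CSD time axis", class = "lamindev_window_error")
  sub <- csd_map$csd[, sel, drop = FALSE]
  t_sub <- csd_map$time[sel]
  sink_val <- apply(sub, 1, min) # sinks are negative
  sink_lat <- t_sub[apply(sub, 1, which.min)]
  mag <- -sink_val
  if (max(mag) <= 0) abort("no sink in the search window", class = "lamindev_no_sink_error")
  qualifies <- mag >= amplitude_fraction * max(mag)
  if (!any(qualifies)) abort("no sink exceeds the amplitude criterion", class = "lamindev_no_sink_error")
  seed <- which(qualifies)[which.min(sink_lat[qualifies])]
  in_range <- function(i) {
    qualifies[i] && abs(sink_lat[i] - sink_lat[seed]) <= latency_tol
  }
  lo <- seed
  while (lo > 1 && in_range(lo - 1)) lo <- lo - 1
  hi <- seed
  while (hi < length(mag) && in_range(hi + 1)) hi <- hi + 1
  structure(
    list(
      granular_channels = lo:hi,
      supragranular_channels = if (lo > 1) 1:(lo - 1) else integer(0),
      infragranular_channels = if (hi < length(mag)) (hi + 1):length(mag) else integer(0),
      sink_channel = seed,
      sink_latency_ms = 1000 * sink_lat[seed],
      sink_amplitude = mag[seed]
    ),
    class = "layer_assignment"
  )
}

#' @export
print.layer_assignment <- function(x, ...) {
  cat(sprintf(
    "<layer_assignment> G: %d-%d (sink ch %d @ %.1f ms) | SG: %d ch | IG: %d ch\n",
    min(x$granular_channels), max(x$granular_channels), x$sink_channel,
    x$sink_latency_ms, length(x$supragranular_channels),
    length(x$infragranular_channels)
  ))
  invisible(x)
}

#' Average the stimulus-aligned LFP and estimate its CSD
#'
#' Convenience wrapper for the usual layer-localization route: align the LFP
#' on the supplied onsets, average across trials, then estimate the CSD of the
#' trial-averaged profile.
#'
#' @param rec A [recording()].
#' @param onsets Stimulus onset times, s.
#' @param window Trial window relative to onset, s.
#' @inheritParams estimate_csd
#' @return A `csd_map` with a time axis relative to stimulus onset.
#' @export
evoked_csd <- function(rec, onsets, window = c(-0.05, 0.15),
                       pair_average = FALSE, smooth = TRUE, vaknin = TRUE) {
  validate_recording(rec)
  fs <- rec$fs_lfp
  i0 <- round(window[1] * fs)
  i1 <- round(window[2] * fs)
  keep <- onsets + window[1] >= 0 & onsets + window[2] <= rec$duration
  onsets <- onsets[keep]
  if (!length(onsets)) abort("no complete trials", class = "lamindev_empty_error")
  acc <- matrix(0, nrow = nrow(rec$lfp), ncol = i1 - i0 + 1)
  for (on in onsets) {
    c0 <- round(on * fs) + 1 + i0
    acc <- acc + rec$lfp[, c0:(c0 + i1 - i0), drop = FALSE]
  }
  avg <- acc / length(onsets)
  estimate_csd(avg, rec$contact_spacing_um,
    time = seq(i0, i1) / fs,
    pair_average = pair_average, smooth = smooth, vaknin = vaknin
  )
}
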
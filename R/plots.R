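# ggplot2 autoplot methods for the main result types

#' Heatmap of a CSD map
#'
#' Sinks (negative CSD) render blue under the default diverging scale.
#'
#' @param object A `csd_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csd_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$channel, fill = .data$csd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(
      x = "time from stimulus (s)", y = "channel (superficial to deep)",
      fill = "CSD", title = "Current-source density (sinks negative)"
    )
}

#' Trace plot of an evoked response
#'
#' @param object An `evoked_response`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evoked_response <- function(object, ...) {
  ylab <- if (object$kind == "mua") "rate (spikes/s per trial)" else "LFP (mV)"
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from stimulus (s)", y = ylab)
}

#' Normalized power spectrum with band shading
#'
#' @param object A `spectral_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_summary <- function(object, ...) {
  bp <- object$band_powers
  ggplot2::ggplot(object$psd, ggplot2::aes(.data$freq, .data$density)) +
    ggplot2::geom_rect(
      data = bp,
      ggplot2::aes(
        xmin = .data$lo_hz, xmax = .data$hi_hz,
        ymin = -Inf, ymax = Inf, fill = .data$band
      ),
      alpha = 0.15, inherit.aes = FALSE
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power density")
}

#' Raster-style overview of detected spindle bursts
#'
#' @param object A `spindle_events` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spindle_events <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$onset_s, xend = .data$onset_s + .data$duration_s,
        y = .data$intra_freq_hz, yend = .data$intra_freq_hz
      ),
      linewidth = 2
    ) +
    ggplot2::labs(
      x = "time (s)", y = "intra-event frequency (Hz)",
      title = sprintf("%d spindle bursts", nrow(df))
    )
}

#' Event-aligned average spectrogram
#'
#' @param object An `event_spectrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.event_spectrogram <- function(object, ...) {
  df <- tibble(
    time = rep(object$time, each = length(object$freqs)),
    freq = rep(object$freqs, times = length(object$time)),
    magnitude = as.vector(object$magnitude)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq, fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "time from event onset (s)", y = "frequency (Hz)",
      title = sprintf("average of %d events", object$n_events)
    )
}

#' Silhouette curve of the staging scan
#'
#' @param object A `staging_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.staging_result <- function(object, ...) {
  ggplot2::ggplot(
    object$silhouette_by_k,
    ggplot2::aes(.data$k, .data$mean_silhouette)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed") +
    ggplot2::labs(x = "k", y = "mean silhouette width")
}
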
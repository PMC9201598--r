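# broom-style tidiers for the package's fitted/derived objects

#' Tidy a CSD map into long format
#'
#' @param x A `csd_map`.
#' @param ... Unused.
#' @return Tibble with `channel`, `time`, `csd`.
#' @export
tidy.csd_map <- function(x, ...) {
  tibble(
    channel = rep(x$depth_index, times = ncol(x$csd)),
    time = rep(x$time, each = nrow(x$csd)),
    csd = as.vector(x$csd)
  )
}

#' Tidy a layer assignment
#'
#' @param x A `layer_assignment`.
#' @param ... Unused.
#' @return Tibble with `channel`, `layer`.
#' @export
tidy.layer_assignment <- function(x, ...) {
  tibble(
    channel = c(
      x$supragranular_channels, x$granular_channels,
      x$infragranular_channels
    ),
    layer = c(
      rep("SG", length(x$supragranular_channels)),
      rep("G", length(x$granular_channels)),
      rep("IG", length(x$infragranular_channels))
    )
  ) |> arrange(.data$channel)
}

#' @export
glance.layer_assignment <- function(x, ...) {
  tibble(
    sink_channel = x$sink_channel,
    sink_latency_ms = x$sink_latency_ms,
    sink_amplitude = x$sink_amplitude,
    n_granular = length(x$granular_channels)
  )
}

#' Tidy an evoked response
#'
#' @param x An `evoked_response`.
#' @param ... Unused.
#' @return Tibble with `time`, `value`, `kind`.
#' @export
tidy.evoked_response <- function(x, ...) {
  tibble(time = x$time, value = x$mean, kind = x$kind)
}

#' Tidy a spectral summary (the normalized density)
#'
#' @param x A `spectral_summary`.
#' @param ... Unused.
#' @return Tibble with `freq`, `density`.
#' @export
tidy.spectral_summary <- function(x, ...) x$psd

#' @export
glance.spectral_summary <- function(x, ...) {
  tidyr::pivot_wider(x$band_powers[, c("band", "power")],
    names_from = "band", values_from = "power"
  )
}

#' Tidy a staging result (per-subject labels)
#'
#' @param x A `staging_result`.
#' @param ... Unused.
#' @return Tibble with `subject`, `cluster` (and `age_days` when known).
#' @export
tidy.staging_result <- function(x, ...) {
  out <- tibble(
    subject = seq_along(x$cluster_labels),
    cluster = as.integer(x$cluster_labels)
  )
  if (!is.null(x$feature_matrix)) {
    out$subject <- x$feature_matrix$subject_ids
    out$age_days <- x$feature_matrix$ages
  }
  out
}

#' @export
glance.staging_result <- function(x, ...) {
  tibble(
    best_k = x$best_k,
    best_silhouette = x$silhouette_by_k$mean_silhouette[
      x$silhouette_by_k$k == x$best_k
    ],
    weak_structure = x$weak_structure,
    n_pcs = if (!is.null(x$pca)) x$pca$n_retained else NA_integer_
  )
}
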
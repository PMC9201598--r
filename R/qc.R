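#' Channel quality control by 50 Hz line-noise excess
#'
#' A contact is analyzable when its 50 Hz power does not stand more than
#' `threshold` standard deviations above the smooth trend of its power
#' spectrum, and when it shows consistent activity (nonzero variance). The
#' spectrum is a Welch estimate (4 s non-overlapping segments); the trend is a
#' running median over a `2 * trend_halfwidth` Hz neighborhood with the
#' 49-51 Hz notch excluded, and the residual SD is taken over `sd_band`
#' (default 20-80 Hz, notch excluded).
#'
#' @param rec A [recording()]; duration must be at least 20 s.
#' @param threshold Keep channels with score below this many SDs (default 2).
#' @param line_freq Line frequency, Hz.
#' @param trend_halfwidth Half-width of the running-median neighborhood, Hz.
#' @param sd_band Frequency range over which residual SD is computed, Hz.
#' @param seg_sec Welch segment length, s.
#' @return A channel-mask tibble: `channel`, `depth_um`, `score_50hz`, `keep`.
#' @export
qc_channels <- function(rec, threshold = 2, line_freq = 50,
                        trend_halfwidth = 2.5, sd_band = c(20, 80),
                        seg_sec = 4) {
  validate_recording(rec)
  if (rec$duration < 20) {
    abort("QC requires at least 20 s of signal", class = "lamindev_length_error")
  }
  notch <- c(line_freq - 1, line_freq + 1)
  score_one <- function(x) {
    if (var(x) == 0) {
      return(Inf) # flat contact: no consistent activity
    }
    psd <- welch_psd(x, rec$fs_lfp, seg_sec = seg_sec)
    lp <- log10(psd$power + .Machine$double.xmin)
    f <- psd$freq
    in_notch <- f > notch[1] & f < notch[2]
    trend_at <- function(f0) {
      sel <- abs(f - f0) <= trend_halfwidth & !in_notch
      median(lp[sel])
    }
    band <- f >= sd_band[1] & f <= sd_band[2] & !in_notch
    resid <- lp[band] - vapply(f[band], trend_at, numeric(1))
    i50 <- which.min(abs(f - line_freq))
    (lp[i50] - trend_at(line_freq)) / sd(resid)
  }
  scores <- apply(rec$lfp, 1, score_one)
  mask <- tibble(
    channel = seq_len(nrow(rec$lfp)),
    depth_um = rec$channel_depths,
    score_50hz = scores,
    keep = is.finite(scores) & scores < threshold
  )
  if (!any(mask$keep)) {
    abort("QC rejected every channel", class = "lamindev_qc_error")
  }
  mask
}

#' Equalize retained channel counts across layers
#'
#' Within each of the supragranular, granular and infragranular groups, retain
#' the minimum across-layer count of QC-kept channels so that every layer
#' contributes the same number of contacts downstream. Surplus channels are
#' dropped deterministically: the channels farthest from the granular
#' sink-center channel go first, ties broken toward keeping the smaller
#' channel index.
#'
#' @param mask Channel-mask tibble from [qc_channels()].
#' @param layers A layer assignment from [assign_layers()].
#' @return The mask tibble with a `layer` column (`SG`/`G`/`IG`) and `keep`
#'   updated to the equalized selection.
#' @export
equalize_layer_counts <- function(mask, layers) {
  mask$layer <- channel_layer(mask$channel, layers)
  kept <- split(mask$channel[mask$keep & !is.na(mask$layer)],
    mask$layer[mask$keep & !is.na(mask$layer)]
  )
  for (ly in c("SG", "G", "IG")) {
    if (is.null(kept[[ly]]) || length(kept[[ly]]) == 0) {
      abort(sprintf("layer %s has no kept channels", ly),
        class = "lamindev_layer_coverage_error"
      )
    }
  }
  n_min <- min(vapply(kept, length, integer(1)))
  center <- layers$sink_channel
  keep_new <- logical(nrow(mask))
  for (ly in names(kept)) {
    ch <- kept[[ly]]
    ord <- order(abs(ch - center), ch) # nearest to sink center, ties -> smaller index
    keep_new[mask$channel %in% ch[ord][seq_len(n_min)]] <- TRUE
  }
  mask$keep <- keep_new
  mask
}

# map channel indices to SG/G/IG labels given a layer assignment
channel_layer <- function(channels, layers) {
  out <- rep(NA_character_, length(channels))
  out[channels %in% layers$supragranular_channels] <- "SG"
  out[channels %in% layers$granular_channels] <- "G"
  out[channels %in% layers$infragranular_channels] <- "IG"
  out
}

#' Write a channel-QC report to CSV
#'
#' @param mask Channel-mask tibble (optionally layer-annotated).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(mask, path) {
  write.csv(mask, path, row.names = FALSE)
  invisible(path)
}
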
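# On-disk container: a directory holding meta.json plus raw little-endian
# float64 payloads (lfp.bin row-major channels x samples; spikes.bin
# concatenated per-channel with counts in the sidecar). Binary payloads make
# the round trip bit-exact, which CSV rendering of doubles cannot guarantee.

#' Write a recording to its on-disk container
#'
#' @param rec A [recording()].
#' @param path Directory to create (must not already contain a recording).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "lamindev-recording-v1",
    n_channels = nrow(rec$lfp),
    n_samples = ncol(rec$lfp),
    fs_lfp = rec$fs_lfp,
    fs_spikes = rec$fs_spikes,
    channel_depths_um = rec$channel_depths,
    contact_spacing_um = rec$contact_spacing_um,
    age_days = rec$age_days,
    genotype = rec$genotype,
    duration_s = rec$duration,
    spike_counts = vapply(rec$spike_times, length, integer(1))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  con <- file(file.path(path, "lfp.bin"), "wb")
  writeBin(as.numeric(t(rec$lfp)), con, size = 8, endian = "little")
  close(con)
  con <- file(file.path(path, "spikes.bin"), "wb")
  writeBin(as.numeric(unlist(rec$spike_times, use.names = FALSE)), con,
    size = 8, endian = "little"
  )
  close(con)
  invisible(path)
}

#' Read a recording from its on-disk container
#'
#' Units are stored and returned as millivolts / seconds / micrometers.
#'
#' @param path Directory written by [write_recording()].
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("no recording container at '%s' (meta.json missing)", path),
      class = "lamindev_format_error"
    )
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c(
    "n_channels", "n_samples", "fs_lfp", "fs_spikes", "channel_depths_um",
    "contact_spacing_um", "age_days", "duration_s", "spike_counts"
  )
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("recording metadata missing field(s): ", paste(miss, collapse = ", ")),
      class = "lamindev_format_error"
    )
  }
  nc <- meta$n_channels
  ns <- meta$n_samples
  con <- file(file.path(path, "lfp.bin"), "rb")
  lfp <- matrix(readBin(con, "double", n = nc * ns, size = 8, endian = "little"),
    nrow = nc, byrow = TRUE
  )
  close(con)
  counts <- meta$spike_counts
  con <- file(file.path(path, "spikes.bin"), "rb")
  flat <- readBin(con, "double", n = sum(counts), size = 8, endian = "little")
  close(con)
  idx <- c(0, cumsum(counts))
  spikes <- lapply(seq_len(nc), function(i) {
    if (counts[i] == 0) numeric(0) else flat[(idx[i] + 1):idx[i + 1]]
  })
  recording(
    lfp = lfp, fs_lfp = meta$fs_lfp, spike_times = spikes,
    fs_spikes = meta$fs_spikes, channel_depths = as.numeric(meta$channel_depths_um),
    contact_spacing_um = meta$contact_spacing_um, age_days = meta$age_days,
    genotype = meta$genotype %||% "WT", duration = meta$duration_s
  )
}

#' Read a stimulus event table from CSV
#'
#' Expected columns: `onset_s`, `kind` (`single`/`paired`), `speed_hz`,
#' `isi_s` (NA for single deflections), `block`.
#'
#' @param path CSV path.
#' @return Validated tibble of stimulus events.
#' @export
read_stimulus_table <- function(path) {
  stim <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_stimulus_table(stim)
  stim
}

#' Write a stimulus event table to CSV
#'
#' @param stim Stimulus tibble (see [read_stimulus_table()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_stimulus_table <- function(stim, path) {
  validate_stimulus_table(stim)
  write.csv(stim, path, row.names = FALSE)
  invisible(path)
}
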
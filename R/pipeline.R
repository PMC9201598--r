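#' Pipeline configuration
#'
#' Parameters steering the end-to-end analysis. Age windows default to the
#' three developmental stages used throughout: critical period (P5-8),
#' pre-active-whisking (P9-11) and active whisking (P12-16).
#'
#' @param out_dir Output directory (`NULL` = return results only).
#' @param qc_threshold 50 Hz QC threshold, SD units.
#' @param search_window Post-stimulus peak/sink search window, s (the upper
#'   bound is generous enough for slow neonatal latencies).
#' @param amplitude_fraction Sink amplitude criterion for layer assignment.
#' @param evoked_window Trial window for evoked averaging, s.
#' @param reference_speed Speed label defining the staging reference
#'   condition.
#' @param age_windows Named list of inclusive postnatal-day ranges.
#' @param variance_target,max_pc,k_range Staging parameters (see
#'   [pca_project()], [kmeans_silhouette_scan()]).
#' @param seed Seed for the staging k-means restarts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL, qc_threshold = 2,
                            search_window = c(0, 0.15),
                            amplitude_fraction = 0.5,
                            evoked_window = c(-0.1, 0.5),
                            reference_speed = 80,
                            age_windows = list(
                              CP = c(5, 8), preAW = c(9, 11), AW = c(12, 16)
                            ),
                            variance_target = 0.75, max_pc = 10,
                            k_range = 2:10, seed = 1) {
  aw <- do.call(rbind, age_windows)
  if (any(diff(as.vector(t(aw))) < 0)) {
    abort("age windows must be ordered and non-overlapping", class = "lamindev_config_error")
  }
  structure(as.list(environment())[setdiff(names(environment()), "aw")],
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = "lamindev_config_error"
    )
  }
  do.call(pipeline_config, vals)
}

#' Map ages to developmental windows
#'
#' @param age_days Integer vector of postnatal days.
#' @param age_windows Named list of inclusive `c(lo, hi)` day ranges.
#' @return Character vector of window labels (`NA` outside all windows).
#' @export
age_window <- function(age_days, age_windows = list(
                         CP = c(5, 8), preAW = c(9, 11), AW = c(12, 16)
                       )) {
  out <- rep(NA_character_, length(age_days))
  for (nm in names(age_windows)) {
    w <- age_windows[[nm]]
    out[age_days >= w[1] & age_days <= w[2]] <- nm
  }
  out
}

# layer-averaged signal over the equalized kept channels of one layer
layer_signal <- function(rec, mask, layer) {
  ch <- mask$channel[mask$keep & !is.na(mask$layer) & mask$layer == layer]
  if (!length(ch)) abort(sprintf("no kept channels in layer %s", layer),
    class = "lamindev_layer_coverage_error"
  )
  colMeans(rec$lfp[ch, , drop = FALSE])
}

#' Analyze a single subject
#'
#' Runs channel QC, CSD-based layer assignment on the reference condition,
#' layer-count equalization, spontaneous-activity characterization on the
#' pre-stimulus baseline, per-speed evoked metrics (LFP and MUA) and
#' per-ISI paired-pulse ratios.
#'
#' @param rec A [recording()].
#' @param stimuli Stimulus tibble (see [read_stimulus_table()]).
#' @param config A [pipeline_config()].
#' @param subject_id Subject identifier carried into the result tables.
#' @return A `subject_result` list of tidy tables and fitted objects.
#' @export
analyze_subject <- function(rec, stimuli, config = pipeline_config(),
                            subject_id = "subject") {
  validate_recording(rec)
  validate_stimulus_table(stimuli)
  fs <- rec$fs_lfp
  aw <- age_window(rec$age_days, config$age_windows)

  mask <- qc_channels(rec, threshold = config$qc_threshold)

  ref <- stimuli[stimuli$kind == "single" & stimuli$speed_hz == config$reference_speed, ]
  if (!nrow(ref)) {
    ref <- stimuli[stimuli$kind == "single", ]
    if (!nrow(ref)) abort("no single-deflection trials", class = "lamindev_empty_error")
  }
  csd <- evoked_csd(rec, ref$onset_s, window = c(-0.05, config$search_window[2] + 0.05),
    smooth = TRUE, vaknin = TRUE
  )
  layers <- assign_layers(csd,
    search_window = config$search_window,
    amplitude_fraction = config$amplitude_fraction
  )
  mask <- equalize_layer_counts(mask, layers)

  # ---- spontaneous baseline -------------------------------------------
  baseline_end <- if (nrow(stimuli)) max(0, min(stimuli$onset_s) - 1) else rec$duration
  spont <- NULL
  if (baseline_end >= 20) {
    g_sig <- layer_signal(rec, mask, "G")[seq_len(round(baseline_end * fs))]
    g_ch <- mask$channel[mask$keep & mask$layer == "G" & !is.na(mask$layer)]
    g_spikes <- sort(unlist(rec$spike_times[g_ch], use.names = FALSE))
    g_spikes <- g_spikes[g_spikes < baseline_end]
    events <- detect_spindle_bursts(g_sig, fs)
    spont <- list(
      spectrum = welch_band_power(g_sig, fs),
      events = events,
      stats = sb_stats(events, baseline_end),
      firing_rate_hz = baseline_firing_rate(g_spikes, baseline_end)
    )
  }

  # ---- evoked responses per speed -------------------------------------
  g_full <- layer_signal(rec, mask, "G")
  g_ch <- mask$channel[mask$keep & mask$layer == "G" & !is.na(mask$layer)]
  g_spk <- sort(unlist(rec$spike_times[g_ch], use.names = FALSE))
  evoked_tbl <- list()
  responses <- list()
  singles <- stimuli[stimuli$kind == "single", ]
  for (sp in unique(singles$speed_hz)) {
    ons <- singles$onset_s[singles$speed_hz == sp]
    lfp_resp <- average_evoked(g_full, fs, ons, window = config$evoked_window)
    mua_resp <- compute_psth(g_spk, ons, window = config$evoked_window)
    pk_lfp <- peak_metrics(lfp_resp, search_window = config$search_window)
    pk_mua <- peak_metrics(mua_resp, search_window = config$search_window)
    evoked_tbl[[length(evoked_tbl) + 1]] <- tibble(
      subject_id = subject_id, genotype = rec$genotype, age_window = aw,
      layer = "G", condition = as.character(sp), modality = c("lfp", "mua"),
      amplitude = c(pk_lfp$amplitude, pk_mua$amplitude),
      latency_ms = c(pk_lfp$latency_ms, pk_mua$latency_ms),
      n_trials = c(lfp_resp$n_trials, mua_resp$n_trials)
    )
    responses[[as.character(sp)]] <- list(lfp = lfp_resp, mua = mua_resp)
  }
  evoked_tbl <- dplyr::bind_rows(evoked_tbl)

  # ---- paired-pulse ratios --------------------------------------------
  ppr_tbl <- list()
  paired <- stimuli[stimuli$kind == "paired", ]
  for (b in unique(paired$block)) {
    rows <- paired[paired$block == b, ]
    isi <- rows$isi_s[1]
    firsts <- rows$onset_s[seq(1, nrow(rows), by = 2)]
    pre <- 0.15
    avg <- average_evoked(g_full, fs, firsts, window = c(-pre, isi + 0.3))
    pp <- paired_pulse_ratio(avg$mean, fs,
      onset1 = pre, onset2 = pre + isi,
      search_window = min(config$search_window[2], isi), polarity = "negative"
    )
    ppr_tbl[[length(ppr_tbl) + 1]] <- dplyr::mutate(pp,
      subject_id = subject_id, genotype = rec$genotype, age_window = aw,
      layer = "G", condition = as.character(isi), .before = 1
    )
  }
  ppr_tbl <- dplyr::bind_rows(ppr_tbl)

  structure(
    list(
      subject_id = subject_id, age_days = rec$age_days, age_window = aw,
      genotype = rec$genotype, qc = mask, csd = csd, layers = layers,
      spontaneous = spont, evoked = evoked_tbl, ppr = ppr_tbl,
      responses = responses, reference_speed = config$reference_speed
    ),
    class = "subject_result"
  )
}

#' Run the full pipeline over a cohort
#'
#' Per subject: QC, CSD + layer assignment, spontaneous-activity metrics,
#' evoked and paired-pulse tables. Cohort level: descriptive condition
#' aggregates and PCA + k-means developmental staging on the reference
#' condition. A failing subject is logged and skipped; the pipeline aborts
#' only when no subject survives. With `out_dir` set, results are written as
#' CSV/JSON plus a manifest (package version, config hash, seed) that fixes
#' every output byte.
#'
#' @param subjects List of subjects: each a list with `recording`, `stimuli`
#'   and optionally `subject_id` (e.g. the output of [generate_cohort()]), or
#'   a character vector of recording container directories, in which case the
#'   stimulus table is read from `<dir>/stimuli.csv`.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: `subjects` (per-subject results),
#'   `aggregates` (named list of condition summaries), `staging`, `skipped`.
#' @export
run_pipeline <- function(subjects, config = pipeline_config()) {
  if (is.character(subjects)) {
    subjects <- lapply(subjects, function(p) {
      list(
        recording = read_recording(p),
        stimuli = read_stimulus_table(file.path(p, "stimuli.csv")),
        subject_id = basename(p)
      )
    })
  }
  if (!length(subjects)) abort("empty cohort", class = "lamindev_empty_error")
  results <- list()
  skipped <- character(0)
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    sid <- s$subject_id %||% sprintf("subject_%02d", i)
    res <- tryCatch(
      analyze_subject(s$recording, s$stimuli, config, subject_id = sid),
      error = function(e) {
        warn(sprintf("subject %s skipped: %s", sid, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) results[[length(results) + 1]] <- res
    if (is.null(res)) skipped <- c(skipped, sid)
  }
  if (!length(results)) abort("all subjects failed", class = "lamindev_empty_error")

  evoked_all <- dplyr::bind_rows(lapply(results, `[[`, "evoked"))
  ppr_all <- dplyr::bind_rows(lapply(results, `[[`, "ppr"))
  aggregates <- list(
    amplitude = condition_aggregate(
      dplyr::filter(evoked_all, .data$modality == "lfp"), "amplitude"
    ),
    latency = condition_aggregate(
      dplyr::filter(
        evoked_all,
        .data$modality == "lfp", !is.na(.data$latency_ms)
      ),
      "latency_ms"
    ),
    ppr = if (nrow(ppr_all)) condition_aggregate(ppr_all, "ppr") else NULL
  )

  staging <- NULL
  if (length(results) >= 3) {
    staging_subjects <- lapply(results, function(r) {
      ref <- r$responses[[as.character(r$reference_speed)]] %||%
        r$responses[[length(r$responses)]]
      list(
        lfp = ref$lfp, mua = ref$mua,
        subject_id = r$subject_id, age_days = r$age_days
      )
    })
    staging <- tryCatch(
      stage_cohort(staging_subjects,
        variance_target = config$variance_target,
        max_pc = config$max_pc, k_range = config$k_range, seed = config$seed
      ),
      error = function(e) {
        warn(sprintf("staging skipped: %s", conditionMessage(e)))
        NULL
      }
    )
  }

  out <- structure(
    list(
      subjects = results, aggregates = aggregates, staging = staging,
      skipped = skipped, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(out, config$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d subjects analyzed, %d skipped%s\n",
    length(x$subjects), length(x$skipped),
    if (!is.null(x$staging)) sprintf(" | staging best k = %d", x$staging$best_k) else ""
  ))
  invisible(x)
}

#' Write a pipeline result to disk
#'
#' One folder per subject (QC report, layer assignment, spindle events and
#' stats, spectrum, evoked and PPR tables) plus cohort aggregates, staging
#' outputs and a reproducibility manifest.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(df) {
    df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 12) else col)
    df
  }
  for (r in result$subjects) {
    sd_dir <- file.path(out_dir, r$subject_id)
    dir.create(sd_dir, showWarnings = FALSE)
    write.csv(num(r$qc), file.path(sd_dir, "qc.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(
        granular = r$layers$granular_channels,
        supragranular = r$layers$supragranular_channels,
        infragranular = r$layers$infragranular_channels,
        sink_channel = r$layers$sink_channel,
        sink_latency_ms = r$layers$sink_latency_ms,
        sink_amplitude = r$layers$sink_amplitude
      ),
      file.path(sd_dir, "layers.json"),
      auto_unbox = TRUE, digits = 12, pretty = TRUE
    )
    if (!is.null(r$spontaneous)) {
      write.csv(num(as.data.frame(r$spontaneous$events)),
        file.path(sd_dir, "sb_events.csv"),
        row.names = FALSE
      )
      write.csv(num(r$spontaneous$stats), file.path(sd_dir, "sb_stats.csv"),
        row.names = FALSE
      )
      write.csv(num(r$spontaneous$spectrum$band_powers),
        file.path(sd_dir, "band_powers.csv"),
        row.names = FALSE
      )
    }
    write.csv(num(r$evoked), file.path(sd_dir, "evoked.csv"), row.names = FALSE)
    if (nrow(r$ppr)) {
      write.csv(num(r$ppr), file.path(sd_dir, "ppr.csv"), row.names = FALSE)
    }
  }
  for (nm in names(result$aggregates)) {
    if (!is.null(result$aggregates[[nm]])) {
      write.csv(num(result$aggregates[[nm]]),
        file.path(out_dir, paste0("aggregate_", nm, ".csv")),
        row.names = FALSE
      )
    }
  }
  if (!is.null(result$staging)) {
    write.csv(
      num(tibble(
        subject_id = result$staging$feature_matrix$subject_ids,
        age_days = result$staging$feature_matrix$ages,
        cluster = result$staging$cluster_labels
      )),
      file.path(out_dir, "staging_labels.csv"),
      row.names = FALSE
    )
    write.csv(num(result$staging$silhouette_by_k),
      file.path(out_dir, "staging_silhouette.csv"),
      row.names = FALSE
    )
  }
  manifest <- list(
    package = "lamindev",
    version = as.character(utils::packageVersion("lamindev")),
    # hash the scientific parameters only, not the output location
    config_hash = rlang::hash(result$config[setdiff(names(result$config), "out_dir")]),
    seed = result$config$seed,
    n_subjects = length(result$subjects),
    skipped = result$skipped
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}
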
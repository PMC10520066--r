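#' Analysis run configuration
#'
#' Bundles every tunable of the end-to-end pipeline. The defaults are the
#' constants of the acquisition and analysis chain the package models:
#' 8 s epochs scored from 16 s Hamming windows with 50% overlap, bouts of
#' at least 6 epochs, 5 h threshold segments, RR resampling at 64 Hz with
#' 1024-point (16 s) spectra, LF 0.06-0.6 Hz and HF 0.6-2.4 Hz bands.
#'
#' @param epoch_len_s Epoch length (s).
#' @param window_s Spectral window length (s).
#' @param min_run Minimum epochs per bout.
#' @param segment_len_h Threshold-segment length (h).
#' @param min_segment_min Minimum minutes for a threshold segment.
#' @param t_mpf,t_emg Optional manual threshold overrides.
#' @param rr_bounds Physiologic RR bounds (ms).
#' @param resample_hz RR resampling rate (Hz).
#' @param nfft HRV segment length (samples).
#' @param hrv_rule Segment-to-stage rule: `"all"` or `"majority"`.
#' @param log_order `"log_of_mean"` or `"mean_of_logs"`.
#' @param stats_policy Test policy for group comparisons.
#' @return A list of class `run_config`.
#' @export
run_config <- function(epoch_len_s = 8, window_s = 16, min_run = 6,
                       segment_len_h = 5, min_segment_min = 30,
                       t_mpf = NULL, t_emg = NULL,
                       rr_bounds = c(100, 350), resample_hz = 64,
                       nfft = 1024, hrv_rule = "all",
                       log_order = "log_of_mean", stats_policy = "auto") {
  cfg <- list(
    epoch_len_s = epoch_len_s, window_s = window_s, min_run = min_run,
    segment_len_h = segment_len_h, min_segment_min = min_segment_min,
    t_mpf = t_mpf, t_emg = t_emg, rr_bounds = rr_bounds,
    resample_hz = resample_hz, nfft = nfft, hrv_rule = hrv_rule,
    log_order = log_order, stats_policy = stats_policy
  )
  class(cfg) <- "run_config"
  cfg
}

# djb2 hash of the deparsed configuration; stamped on every output table
# so results from different configurations cannot be mixed silently.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Run the full analysis pipeline on one recording
#'
#' EEG/EMG: sliding spectra, per-epoch features, per-segment histogram
#' thresholds, AW/QS/PS/ERR classification, bout formation and architecture
#' metrics. ECG: R-peak detection, artifact-masked tachogram, 64 Hz
#' resampling, 16 s LF/HF spectra, stage conditioning. A run log records
#' thresholds, overrides, mask counts and warnings.
#'
#' @param rec A `somnark_recording` (synthetic or read from file).
#' @param config A [run_config()].
#' @return An object of class `somnark_result`: a list with `features`,
#'   `thresholds`, `labeled`, `staged`, `architecture`, `tachogram`,
#'   `hrv_segments`, `stage_hrv`, `config`, `config_hash`, `log`.
#' @export
run_pipeline <- function(rec, config = run_config()) {
  stopifnot(inherits(rec, "somnark_recording"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  hash <- config_hash(config)

  hop_s <- config$window_s / 2
  eeg_spec <- sliding_spectrum(rec$eeg, rec$fs[["eeg"]],
                               window_s = config$window_s, hop_s = hop_s)
  emg_spec <- sliding_spectrum(rec$emg, rec$fs[["emg"]],
                               window_s = config$window_s, hop_s = hop_s)
  features <- epoch_features(eeg_spec, emg_spec)
  note("features: ", nrow(features), " epochs")

  thresholds <- withCallingHandlers(
    estimate_thresholds(features, segment_len_h = config$segment_len_h,
                        min_segment_min = config$min_segment_min,
                        t_mpf = config$t_mpf, t_emg = config$t_emg,
                        epoch_len_s = config$epoch_len_s),
    warning = function(w) {
      note("threshold warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  for (i in seq_len(nrow(thresholds))) {
    note(sprintf("segment %d: t_mpf=%.3f Hz, t_emg=%.4g (%s)",
                 thresholds$segment_id[i], thresholds$t_mpf[i],
                 thresholds$t_emg[i], thresholds$source[i]))
  }

  labeled <- classify_epochs(features, thresholds)
  note("ERR epochs: ", sum(labeled$label == "ERR"))
  staged <- form_stages(labeled, min_run = config$min_run,
                        epoch_len_s = config$epoch_len_s)
  architecture <- architecture_metrics(labeled, staged,
                                       epoch_len_s = config$epoch_len_s)

  beats <- detect_r_peaks(rec$ecg, rec$fs[["ecg"]])
  note("beats detected: ", length(beats))
  tacho <- rr_tachogram(beats, bounds = config$rr_bounds)
  note("RR intervals masked: ", sum(tacho$artifact))
  uniform <- resample_rr(tacho, rate = config$resample_hz)
  segments <- hrv_spectra(uniform, nfft = config$nfft)
  stage_hrv <- stage_conditioned_hrv(
    segments, labeled, epoch_len_s = config$epoch_len_s,
    rule = config$hrv_rule, log_order = config$log_order,
    window_s = config$nfft / config$resample_hz
  )

  structure(
    list(features = features, thresholds = thresholds, labeled = labeled,
         staged = staged, architecture = architecture, tachogram = tacho,
         hrv_segments = attr(stage_hrv, "segments"), stage_hrv = stage_hrv,
         config = config, config_hash = hash,
         provenance = rec$provenance, log = log),
    class = "somnark_result"
  )
}

#' @export
print.somnark_result <- function(x, ...) {
  cat("<somnark_result> config", x$config_hash, "\n")
  print(x$architecture)
  cat("  HRV strata:", paste(x$stage_hrv$stratum, collapse = ", "), "\n")
  invisible(x)
}

#' One-row summary of a pipeline result
#'
#' @param x A `somnark_result`.
#' @param ... Unused.
#' @return A one-row tibble: stage percentages, interruption rates, overall
#'   mean RR and log LF/HF, epoch and beat counts.
#' @method glance somnark_result
#' @export
glance.somnark_result <- function(x, ...) {
  ov <- x$stage_hrv[x$stage_hrv$stratum == "overall", ]
  tibble::tibble(
    n_epochs = nrow(x$labeled),
    aw_pct = x$architecture$time_pct[["AW"]],
    qs_pct = x$architecture$time_pct[["QS"]],
    ps_pct = x$architecture$time_pct[["PS"]],
    interruption_per_min = x$architecture$interruption_rate,
    qs_interruption_per_min = x$architecture$qs_interruption_rate,
    mean_rr_ms = ov$mean_rr_ms, log_lfhf = ov$log_lfhf,
    config_hash = x$config_hash
  )
}

#' Extract per-animal metrics from a pipeline result
#'
#' Flattens one recording's sleep-architecture and stage-conditioned HRV
#' summaries into the long metric format consumed by [build_report()]:
#' stage percentages, interruption rates, QS band percentages, and per-
#' stratum RR / log LF / log HF / log LF-HF. Each row carries the run's
#' config hash so results from different configurations cannot be pooled.
#'
#' @param result A `somnark_result`.
#' @param animal_id Identifier for the animal/recording.
#' @param group Group label.
#' @return A tibble with `animal_id`, `group`, `metric`, `value`,
#'   `config_hash`.
#' @export
pipeline_metrics <- function(result, animal_id, group) {
  arch <- tidy(result$architecture)
  hrv <- result$stage_hrv |>
    tidyr::pivot_longer(c("mean_rr_ms", "log_lf", "log_hf", "log_lfhf"),
                        names_to = "what", values_to = "value") |>
    dplyr::transmute(metric = paste0(.data$what, "_", .data$stratum),
                     value = .data$value)
  dplyr::bind_rows(arch, hrv) |>
    dplyr::mutate(animal_id = animal_id, group = group,
                  config_hash = result$config_hash, .before = 1)
}

#' Combine per-animal metric tables for group comparison
#'
#' @param ... Tibbles from [pipeline_metrics()].
#' @return A single tibble; errors if the inputs carry different config
#'   hashes.
#' @export
bind_metrics <- function(...) {
  out <- dplyr::bind_rows(...)
  if ("config_hash" %in% names(out) &&
      length(unique(out$config_hash)) > 1) {
    stop("refusing to mix metric tables from different config hashes",
         call. = FALSE)
  }
  out
}

#' Write all pipeline result tables to a directory
#'
#' Writes the feature table, hypnogram and bout tables, architecture
#' report, HRV segment and stage-summary tables, the run log and a
#' provenance JSON (config, hash, seed when synthetic).
#'
#' @param result A `somnark_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_features_csv(result$features, file.path(dir, "features.csv"))
  write_hypnogram_csv(result$labeled, result$staged, dir)
  write.csv(tidy(result$architecture), file.path(dir, "architecture.csv"),
            row.names = FALSE)
  write_hrv_csv(result$stage_hrv, dir)
  writeLines(result$log, file.path(dir, "run_log.txt"))
  jsonlite::write_json(
    list(config_hash = result$config_hash,
         config = unclass(result$config),
         provenance = result$provenance),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, null = "null",
    digits = NA
  )
  invisible(dir)
}
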
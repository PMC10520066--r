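#' Build a validated synthetic-recording configuration
#'
#' A `sim_config` fixes every parameter of the synthetic polysomnography
#' generator: the hypnogram structure (mean bout lengths, target stage mix,
#' quiet-sleep interruption rate), the state-dependent EEG band composition
#' and EMG amplitude, and the beat-interval dynamics of the ECG
#' (mean RR plus per-stage LF- and HF-band sinusoidal modulation).
#'
#' @param duration_min Recording length in minutes.
#' @param epoch_len_s Epoch length in seconds (the classification unit; 8 s).
#' @param stage_mean_bouts Named numeric (AW, QS, PS): mean bout length in
#'   epochs for each stage. Must be positive.
#' @param stage_mix Named numeric (AW, QS, PS): target fraction of time in
#'   each stage; non-negative, summing to 1.
#' @param qs_interruption_rate Rate (events per minute of quiet sleep) at
#'   which short (1-5 epoch) active-waking intrusions are injected into QS
#'   bouts, emulating sleep fragmentation.
#' @param eeg_band_weights Named list (AW, QS, PS), each a numeric of 4
#'   relative powers (delta, theta, alpha, beta) for that stage's EEG.
#' @param emg_gain Named numeric (AW, QS, PS): RMS amplitude of the
#'   band-limited (34-103 Hz) EMG noise per stage, arbitrary units.
#' @param mean_rr Mean RR interval in ms.
#' @param rr_lf_amp,rr_hf_amp Named numeric (AW, QS, PS): amplitude (ms) of
#'   the sinusoidal RR modulation in the LF and HF band per stage.
#' @param lf_mod_freq,hf_mod_freq Modulation frequencies in Hz; must lie in
#'   \[0.06, 0.6) and \[0.6, 2.4\] respectively.
#' @param rr_noise_sd Standard deviation (ms) of the broadband RR noise.
#' @param seed Integer seed; the same (config, seed) pair always reproduces
#'   the same recording.
#'
#' @return A list of class `sim_config`.
#' @seealso [sim_config_control()], [sim_config_pm25()], [generate_recording()]
#' @export
sim_config <- function(duration_min = 30,
                       epoch_len_s = 8,
                       stage_mean_bouts = c(AW = 12, QS = 20, PS = 12),
                       stage_mix = c(AW = 0.11, QS = 0.48, PS = 0.41),
                       qs_interruption_rate = 0.35,
                       eeg_band_weights = list(
                         AW = c(0.30, 0.40, 0.10, 0.20),
                         QS = c(0.88, 0.07, 0.025, 0.025),
                         PS = c(0.20, 0.55, 0.15, 0.10)
                       ),
                       emg_gain = c(AW = 10, QS = 1, PS = 0.8),
                       mean_rr = 198,
                       rr_lf_amp = c(AW = 4.8, QS = 4.1, PS = 5.2),
                       rr_hf_amp = c(AW = 3.0, QS = 3.0, PS = 3.2),
                       lf_mod_freq = 0.3,
                       hf_mod_freq = 1.2,
                       rr_noise_sd = 2,
                       seed = 0L) {
  cfg <- list(
    duration_min = duration_min, epoch_len_s = epoch_len_s,
    stage_mean_bouts = stage_mean_bouts, stage_mix = stage_mix,
    qs_interruption_rate = qs_interruption_rate,
    eeg_band_weights = eeg_band_weights, emg_gain = emg_gain,
    mean_rr = mean_rr, rr_lf_amp = rr_lf_amp, rr_hf_amp = rr_hf_amp,
    lf_mod_freq = lf_mod_freq, hf_mod_freq = hf_mod_freq,
    rr_noise_sd = rr_noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(cfg$duration_min > 0)) stop("duration must be positive", call. = FALSE)
  if (cfg$epoch_len_s <= 0) stop("epoch length must be positive", call. = FALSE)
  for (nm in c("stage_mean_bouts", "stage_mix", "emg_gain",
               "rr_lf_amp", "rr_hf_amp")) {
    v <- cfg[[nm]]
    if (!all(STAGES %in% names(v))) {
      stop(nm, " must be named with AW, QS, PS", call. = FALSE)
    }
  }
  if (any(cfg$stage_mean_bouts <= 0)) {
    stop("mean bout lengths must be positive", call. = FALSE)
  }
  if (any(cfg$stage_mix < 0) || abs(sum(cfg$stage_mix) - 1) > 1e-8) {
    stop("stage_mix must be non-negative and sum to 1", call. = FALSE)
  }
  if (cfg$qs_interruption_rate < 0) {
    stop("qs_interruption_rate must be non-negative", call. = FALSE)
  }
  if (!all(STAGES %in% names(cfg$eeg_band_weights)) ||
      !all(vapply(cfg$eeg_band_weights, length, 1L) == 4) ||
      any(unlist(cfg$eeg_band_weights) < 0)) {
    stop("eeg_band_weights must give 4 non-negative weights per stage",
         call. = FALSE)
  }
  if (!(cfg$mean_rr > 0)) stop("mean_rr must be positive", call. = FALSE)
  if (any(cfg$emg_gain < 0) || any(cfg$rr_lf_amp < 0) ||
      any(cfg$rr_hf_amp < 0) || cfg$rr_noise_sd < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (cfg$lf_mod_freq < LF_BAND[1] || cfg$lf_mod_freq >= LF_BAND[2]) {
    stop("lf_mod_freq must lie in [0.06, 0.6) Hz", call. = FALSE)
  }
  if (cfg$hf_mod_freq < HF_BAND[1] || cfg$hf_mod_freq > HF_BAND[2]) {
    stop("hf_mod_freq must lie in [0.6, 2.4] Hz", call. = FALSE)
  }
  if (max(cfg$rr_lf_amp + cfg$rr_hf_amp) >= cfg$mean_rr) {
    stop("modulation amplitudes must be smaller than mean_rr", call. = FALSE)
  }
  invisible(cfg)
}

#' Control-like and exposure-like generator presets
#'
#' Two ready-made configurations that mimic, at the signal-statistics level,
#' the sleep/HRV phenotypes of an unexposed control rat and of a rat after
#' acute fine-particulate (PM2.5) aerosol exposure: the exposure-like preset
#' has a higher quiet-sleep interruption rate and stronger LF RR modulation
#' during quiet sleep (raising QS log LF/HF by about 0.5), with a slightly
#' less delta-dominant QS EEG. Neither preset models toxicology; they exist
#' so that the two-group pipeline has realistic, separable inputs.
#'
#' @param duration_min Recording length in minutes.
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
sim_config_control <- function(duration_min = 30, seed = 0L) {
  sim_config(duration_min = duration_min, seed = seed)
}

#' @rdname sim_config_control
#' @export
sim_config_pm25 <- function(duration_min = 30, seed = 0L) {
  sim_config(
    duration_min = duration_min, seed = seed,
    stage_mix = c(AW = 0.11, QS = 0.60, PS = 0.29),
    qs_interruption_rate = 0.52,
    eeg_band_weights = list(
      AW = c(0.30, 0.40, 0.10, 0.20),
      QS = c(0.83, 0.09, 0.037, 0.043),
      PS = c(0.20, 0.55, 0.15, 0.10)
    ),
    rr_lf_amp = c(AW = 5.8, QS = 5.3, PS = 5.9),
    rr_hf_amp = c(AW = 3.0, QS = 3.0, PS = 3.2)
  )
}

#' Read or write a generator configuration as JSON
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  out <- lapply(unclass(cfg), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$eeg_band_weights <- lapply(raw$eeg_band_weights, as.numeric)
  cfg <- do.call(sim_config, c(
    list(
      duration_min = raw$duration_min, epoch_len_s = raw$epoch_len_s,
      stage_mean_bouts = unlist(raw$stage_mean_bouts),
      stage_mix = unlist(raw$stage_mix),
      qs_interruption_rate = raw$qs_interruption_rate,
      eeg_band_weights = raw$eeg_band_weights,
      emg_gain = unlist(raw$emg_gain),
      mean_rr = raw$mean_rr,
      rr_lf_amp = unlist(raw$rr_lf_amp), rr_hf_amp = unlist(raw$rr_hf_amp),
      lf_mod_freq = raw$lf_mod_freq, hf_mod_freq = raw$hf_mod_freq,
      rr_noise_sd = raw$rr_noise_sd, seed = raw$seed
    )
  ))
  cfg
}
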
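# Child seeds: one global seed fans out to per-channel streams by fixed
# offsets so channels are independent but jointly reproducible.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 97561L * k) %% 2147483647)
}

stage_of_epoch <- function(labels, n_samples, fs, epoch_len_s) {
  idx <- pmin(floor(seq_len(n_samples) - 1) %/% (fs * epoch_len_s) + 1,
              length(labels))
  labels[idx]
}

#' Simulate a ground-truth hypnogram
#'
#' Draws a semi-Markov sequence of AW/QS/PS epochs: bout lengths are
#' geometric with the configured per-stage means, stages are entered with
#' probability proportional to `stage_mix / stage_mean_bouts` (so the time
#' fractions converge to `stage_mix`), and short (1-5 epoch) active-waking
#' intrusions are injected into quiet-sleep bouts as a Poisson process at
#' `qs_interruption_rate` events per minute of QS.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return A list with `labels` (character vector, one per epoch),
#'   `injected` (tibble of injected intrusions: `start_epoch`, `n_epochs`)
#'   and `n_epochs`.
#' @export
simulate_stage_sequence <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n_epochs <- round(config$duration_min * 60 / config$epoch_len_s)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 1L))

  # Injected AW intrusions convert QS time to AW (mean intrusion ~3 epochs);
  # inflate the pre-injection QS share so the post-injection mix matches the
  # configured target.
  loss <- min(0.9, config$qs_interruption_rate * 3 * config$epoch_len_s / 60)
  mix <- config$stage_mix[STAGES]
  pre <- mix
  pre[["QS"]] <- mix[["QS"]] / (1 - loss)
  pre[["AW"]] <- max(0, mix[["AW"]] - pre[["QS"]] * loss)
  pre <- pre / sum(pre)

  # Visit rates v ~ time-share / mean bout length; a reversible zero-diagonal
  # transition matrix with stationary visit distribution v keeps the realized
  # time fractions at the target mix.
  v <- pre / config$stage_mean_bouts[STAGES]
  v <- v / sum(v)
  cm <- matrix(0, 3, 3, dimnames = list(STAGES, STAGES))
  cpair <- function(i, j, k) min(max(0, (v[i] + v[j] - v[k]) / 2), v[i], v[j])
  cm["AW", "QS"] <- cm["QS", "AW"] <- cpair(1, 2, 3)
  cm["AW", "PS"] <- cm["PS", "AW"] <- cpair(1, 3, 2)
  cm["QS", "PS"] <- cm["PS", "QS"] <- cpair(2, 3, 1)

  labels <- character(0)
  cur <- STAGES[sample.int(3, 1, prob = v)]
  while (length(labels) < n_epochs) {
    m <- config$stage_mean_bouts[[cur]]
    len <- 1L + stats::rgeom(1, prob = min(1, 1 / m))
    labels <- c(labels, rep(cur, len))
    w_next <- cm[cur, ]
    cur <- if (sum(w_next) > 0) STAGES[sample.int(3, 1, prob = w_next)]
           else cur
  }
  labels <- labels[seq_len(n_epochs)]

  # Poisson-process AW intrusions into QS: each QS epoch can start an
  # intrusion with probability rate * epoch_len / 60.
  p_start <- config$qs_interruption_rate * config$epoch_len_s / 60
  starts <- integer(0)
  lens <- integer(0)
  if (p_start > 0) {
    u <- runif(n_epochs)
    draw_len <- sample(1:5, n_epochs, replace = TRUE)
    # interior placement: an intrusion sits WITHIN a QS bout, leaving at
    # least one QS epoch on each side
    i <- 2L
    while (i < n_epochs) {
      if (labels[i] == "QS" && labels[i - 1] == "QS" && u[i] < p_start) {
        run_end <- i
        while (run_end < n_epochs && labels[run_end + 1] == "QS") {
          run_end <- run_end + 1L
        }
        len <- min(draw_len[i], run_end - i) # keep one trailing QS epoch
        if (len >= 1) {
          labels[i:(i + len - 1)] <- "AW"
          starts <- c(starts, i)
          lens <- c(lens, len)
          i <- i + len + 2L # gap so neighbouring intrusions cannot merge
        } else {
          i <- i + 1L
        }
      } else {
        i <- i + 1L
      }
    }
  }
  list(
    labels = labels,
    injected = tibble::tibble(start_epoch = starts, n_epochs = lens),
    n_epochs = n_epochs
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Smooth a per-sample step function with a centered moving average so state
# changes cross-fade linearly over <= ramp_s seconds (no clicks at epoch
# joins). Cumsum form keeps it O(n).
crossfade <- function(g, fs, ramp_s = 0.5) {
  w <- max(1L, round(fs * ramp_s))
  half <- w %/% 2
  n <- length(g)
  cs <- cumsum(c(0, g))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Zero-phase Butterworth band-pass: the |H(f)|^2 magnitude response of the
# designed filter (forward-backward application) applied exactly in the
# frequency domain. `order` is the analogue low-pass prototype order, so
# order = 2 gives the 4th-order band-pass.
zerophase_bandpass <- function(x, fs, band, order = 2) {
  n <- length(x)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  # |H|^2 is smooth: evaluate on a 4096-point grid and interpolate onto the
  # FFT bin frequencies
  ngrid <- 4096L
  wg <- pi * (0:ngrid) / ngrid
  zg <- exp(-1i * wg)
  horner <- function(coef) {
    acc <- rep(coef[1] + 0i, ngrid + 1L)
    for (c in coef[-1]) acc <- acc * zg + c
    acc
  }
  H2g <- Mod(horner(bf$b) / horner(bf$a))^2
  k <- 0:(n - 1)
  w <- 2 * pi * pmin(k, n - k) / n
  H2 <- approx(wg, H2g, xout = w)$y
  Re(fft(fft(x) * H2, inverse = TRUE)) / n
}

band_noise <- function(n, fs, band, order = 4) {
  y <- zerophase_bandpass(rnorm(n), fs, band, order)
  y / sd(y)
}

#' Synthesize a state-dependent EEG trace
#'
#' Per stage, the EEG is a sum of four band-limited Gaussian noise
#' components (delta 1-4, theta 4-8, alpha 8-13, beta 13-32 Hz; 4th-order
#' Butterworth band-pass applied forward-backward) whose powers are
#' proportional to the configured per-stage band weights. Component gains
#' cross-fade over 0.5 s at stage changes.
#'
#' @param labels Character vector of per-epoch stage labels (AW/QS/PS).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Numeric trace sampled at 125 Hz, length
#'   `length(labels) * epoch_len_s * 125`.
#' @export
synthesize_eeg <- function(labels, config, seed = config$seed) {
  stopifnot(length(labels) > 0)
  if (!all(labels %in% STAGES)) stop("unknown stage label", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 2L))
  fs <- FS_EEG
  n <- length(labels) * config$epoch_len_s * fs
  wts <- lapply(config$eeg_band_weights, function(w) w / sum(w))
  st <- stage_of_epoch(labels, n, fs, config$epoch_len_s)
  out <- numeric(n)
  for (b in seq_along(EEG_BANDS)) {
    noise <- band_noise(n, fs, EEG_BANDS[[b]])
    gain <- sqrt(vapply(wts, `[`, numeric(1), b))[st]
    out <- out + noise * crossfade(gain, fs)
  }
  out
}

#' Synthesize a state-dependent EMG trace
#'
#' Gaussian noise band-limited to the 34-103 Hz acquisition passband with a
#' per-stage RMS amplitude (`emg_gain`), cross-faded at stage changes.
#'
#' @inheritParams synthesize_eeg
#' @return Numeric trace sampled at 250 Hz.
#' @export
synthesize_emg <- function(labels, config, seed = config$seed) {
  stopifnot(length(labels) > 0)
  if (!all(labels %in% STAGES)) stop("unknown stage label", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 3L))
  fs <- FS_EMG
  n <- length(labels) * config$epoch_len_s * fs
  if (all(config$emg_gain == 0)) return(numeric(n))
  st <- stage_of_epoch(labels, n, fs, config$epoch_len_s)
  noise <- band_noise(n, fs, EMG_BAND)
  noise * crossfade(config$emg_gain[st], fs)
}

#' Synthesize an ECG trace by integral pulse frequency modulation
#'
#' The instantaneous RR interval is
#' `RR(t) = mean_rr + lf_amp[stage] sin(2 pi f_lf t) + hf_amp[stage]
#' sin(2 pi f_hf t) + noise(t)` (ms); a beat fires whenever the integral of
#' the instantaneous rate `1000/RR(t)` crosses an integer (IPFM model). A
#' 40 ms raised-cosine spike of unit amplitude is placed at each beat — a
#' minimal QRS surrogate adequate for R-peak detection.
#'
#' @inheritParams synthesize_eeg
#' @return A list with `trace` (numeric @ 500 Hz) and `beat_times`
#'   (seconds, strictly increasing ground truth).
#' @export
synthesize_ecg <- function(labels, config, seed = config$seed) {
  stopifnot(length(labels) > 0, config$mean_rr > 0)
  if (max(config$rr_lf_amp + config$rr_hf_amp) >= config$mean_rr) {
    stop("modulation amplitudes must be smaller than mean_rr", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 4L))
  fs <- FS_ECG
  n <- length(labels) * config$epoch_len_s * fs
  t <- (seq_len(n) - 1) / fs
  st <- stage_of_epoch(labels, n, fs, config$epoch_len_s)

  rr_ms <- config$mean_rr +
    config$rr_lf_amp[st] * sin(2 * pi * config$lf_mod_freq * t) +
    config$rr_hf_amp[st] * sin(2 * pi * config$hf_mod_freq * t)
  if (config$rr_noise_sd > 0) {
    # broadband beat-scale noise: white knots every 0.25 s, linear interp
    knots_t <- seq(0, t[n], by = 0.25)
    knots <- rnorm(length(knots_t), sd = config$rr_noise_sd)
    rr_ms <- rr_ms + approx(knots_t, knots, xout = t, rule = 2)$y
  }
  rr_ms <- pmax(rr_ms, 1) # guard against pathological noise draws

  rate <- 1000 / rr_ms # beats per second
  cum <- cumsum(rate) / fs
  k <- seq_len(floor(cum[n]))
  beat_times <- approx(cum, t, xout = k, ties = "ordered")$y

  trace <- numeric(n)
  tpl_n <- round(0.040 * fs) # 40 ms
  tpl <- 0.5 * (1 - cos(2 * pi * seq_len(tpl_n) / (tpl_n + 1)))
  centers <- round(beat_times * fs) + 1L
  half <- tpl_n %/% 2
  for (c0 in centers) {
    i0 <- c0 - half
    idx <- seq(i0, i0 + tpl_n - 1L)
    ok <- idx >= 1 & idx <= n
    trace[idx[ok]] <- trace[idx[ok]] + tpl[ok]
  }
  list(trace = trace, beat_times = beat_times)
}

#' Generate a complete synthetic polysomnography recording
#'
#' Bundles a ground-truth hypnogram with EEG (125 Hz), EMG (250 Hz) and ECG
#' (500 Hz) traces generated under one configuration. All randomness flows
#' from a single seed expanded into fixed per-channel child streams, so the
#' same (config, seed) pair always reproduces the same recording.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return An object of class `somnark_recording`: a list with `eeg`, `emg`,
#'   `ecg` traces, `fs` (named sampling rates), `epoch_len_s`, `truth`
#'   (labels, beat_times, injected intrusions) and `config`.
#' @export
generate_recording <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  hyp <- simulate_stage_sequence(config, seed)
  ecg <- synthesize_ecg(hyp$labels, config, seed)
  rec <- list(
    eeg = synthesize_eeg(hyp$labels, config, seed),
    emg = synthesize_emg(hyp$labels, config, seed),
    ecg = ecg$trace,
    fs = c(eeg = FS_EEG, emg = FS_EMG, ecg = FS_ECG),
    epoch_len_s = config$epoch_len_s,
    duration_s = config$duration_min * 60,
    truth = list(
      labels = hyp$labels,
      beat_times = ecg$beat_times,
      injected = hyp$injected
    ),
    config = config,
    provenance = list(source = "synthetic", seed = as.integer(seed))
  )
  class(rec) <- "somnark_recording"
  rec
}

#' @export
print.somnark_recording <- function(x, ...) {
  cat("<somnark_recording> ", x$duration_s / 60, " min; ",
      length(x$truth$labels), " epochs of ", x$epoch_len_s, " s\n", sep = "")
  cat("  channels: EEG @", x$fs["eeg"], "Hz, EMG @", x$fs["emg"],
      "Hz, ECG @", x$fs["ecg"], "Hz\n")
  if (!is.null(x$truth)) {
    tb <- table(factor(x$truth$labels, STAGES))
    cat("  truth: ", paste(names(tb), round(100 * tb / sum(tb)), "%",
                           collapse = ", "),
        "; ", length(x$truth$beat_times), " beats\n", sep = "")
  }
  invisible(x)
}
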
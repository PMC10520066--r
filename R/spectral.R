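# One-sided Hamming-tapered periodogram of a demeaned window, normalized so
# that the summed bin power equals the taper-corrected window variance
# (Parseval): sum(P) = sum((x w)^2) / sum(w^2).
hamming_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  X <- fft(xw)
  p <- Mod(X)^2 / (n * sum(w^2))
  half <- n %/% 2
  out <- p[1:(half + 1)]
  out[2:half] <- 2 * out[2:half] # fold negative frequencies
  list(freq = (0:half) * fs / n, power = out)
}

#' Sliding-window power spectra of a trace
#'
#' Cuts the trace into 16 s windows with 50% overlap (8 s hop), and for each
#' window computes a mean-removed, Hamming-tapered FFT periodogram whose
#' summed bin power equals the tapered window variance (Parseval). The
#' frequency resolution is 1/16 Hz.
#'
#' @param trace Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s,hop_s Window length and hop in seconds.
#' @return A `somnark_spectrogram`: list with `times` (window start, s),
#'   `freqs` (Hz, 0..Nyquist) and `power` (windows x freqs matrix).
#' @export
sliding_spectrum <- function(trace, fs, window_s = 16, hop_s = 8) {
  nwin <- round(window_s * fs)
  nhop <- round(hop_s * fs)
  if (length(trace) < nwin) {
    stop("trace shorter than one ", window_s, " s window", call. = FALSE)
  }
  n_windows <- (length(trace) - nwin) %/% nhop + 1L
  starts <- (seq_len(n_windows) - 1L) * nhop
  first <- hamming_periodogram(trace[1:nwin], fs)
  power <- matrix(0, n_windows, length(first$freq))
  power[1, ] <- first$power
  if (n_windows > 1) {
    for (i in 2:n_windows) {
      seg <- trace[(starts[i] + 1):(starts[i] + nwin)]
      power[i, ] <- hamming_periodogram(seg, fs)$power
    }
  }
  structure(
    list(times = starts / fs, freqs = first$freq, power = power, fs = fs,
         window_s = window_s, hop_s = hop_s),
    class = "somnark_spectrogram"
  )
}

# Select bin indices for [lo, hi) or [lo, hi] bands on a frequency axis.
band_bins <- function(freqs, band, closed_upper = FALSE) {
  if (closed_upper) {
    which(freqs >= band[1] & freqs <= band[2] + 1e-9)
  } else {
    which(freqs >= band[1] & freqs < band[2] - 1e-9)
  }
}

#' Mean power frequency of a spectrum
#'
#' The power-weighted mean frequency `sum(f P(f)) / sum(P(f))` over the
#' integration band (default 1-32 Hz, the union of the delta through beta
#' bands). High MPF marks active waking and paradoxical sleep; low MPF marks
#' quiet sleep.
#'
#' @param power Numeric vector of bin powers (one spectrogram row).
#' @param freqs Frequency axis in Hz.
#' @param band Integration band, Hz (upper edge included).
#' @return Mean power frequency in Hz.
#' @export
mean_power_frequency <- function(power, freqs, band = c(1, 32)) {
  if (band[1] < min(freqs) || band[2] > max(freqs)) {
    stop("band outside the frequency axis", call. = FALSE)
  }
  i <- band_bins(freqs, band, closed_upper = TRUE)
  tot <- sum(power[i])
  if (tot <= 0) stop("zero in-band power", call. = FALSE)
  sum(freqs[i] * power[i]) / tot
}

#' Delta/theta/alpha/beta band-power fractions
#'
#' Fractions of total 1-32 Hz power in the delta (1-4), theta (4-8),
#' alpha (8-13) and beta (13-32 Hz) bands. Band edges are half-open
#' \[lo, hi): a bin at exactly 4 Hz counts as theta; the top beta edge is
#' closed so the four bands partition 1-32 Hz and the fractions sum to 1.
#'
#' @inheritParams mean_power_frequency
#' @return Named numeric: `delta`, `theta`, `alpha`, `beta` fractions.
#' @export
band_power_fractions <- function(power, freqs) {
  if (max(freqs) < 32) stop("frequency axis must cover 1-32 Hz", call. = FALSE)
  idx <- lapply(seq_along(EEG_BANDS), function(b) {
    band_bins(freqs, EEG_BANDS[[b]], closed_upper = (b == length(EEG_BANDS)))
  })
  pows <- vapply(idx, function(i) sum(power[i]), numeric(1))
  tot <- sum(pows)
  if (tot <= 0) stop("zero total power in 1-32 Hz", call. = FALSE)
  stats::setNames(pows / tot, names(EEG_BANDS))
}

#' EMG band power
#'
#' Summed spectral power over the 34-103 Hz EMG passband (upper edge
#' included).
#'
#' @inheritParams mean_power_frequency
#' @param band Band in Hz.
#' @return Summed in-band power (squared signal units).
#' @export
emg_band_power <- function(power, freqs, band = EMG_BAND) {
  if (band[2] > max(freqs) + 1e-9) {
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  }
  sum(power[band_bins(freqs, band, closed_upper = TRUE)])
}

#' Per-epoch spectral features from EEG and EMG spectrograms
#'
#' Epoch k (8 s) receives the features of the 16 s window starting at the
#' epoch's start (the window covers this epoch and the next); the trailing
#' epoch with no full window is dropped. Features are the EEG mean power
#' frequency, the EMG 34-103 Hz power, and the four EEG band fractions.
#'
#' @param eeg_spec,emg_spec Spectrograms from [sliding_spectrum()] of the
#'   EEG (125 Hz) and EMG (250 Hz) channels over the same time span.
#' @return A tibble with one row per epoch: `epoch_index` (1-based),
#'   `t_start_s`, `mpf_hz`, `emg_power`, `delta_fr`, `theta_fr`, `alpha_fr`,
#'   `beta_fr`.
#' @export
epoch_features <- function(eeg_spec, emg_spec) {
  if (nrow(eeg_spec$power) != nrow(emg_spec$power) ||
      max(abs(eeg_spec$times - emg_spec$times)) > 1e-9) {
    stop("EEG and EMG spectrograms cover different time spans", call. = FALSE)
  }
  n <- nrow(eeg_spec$power)
  fr_eeg <- eeg_spec$freqs
  P <- eeg_spec$power
  band_pow <- vapply(seq_along(EEG_BANDS), function(b) {
    i <- band_bins(fr_eeg, EEG_BANDS[[b]],
                   closed_upper = (b == length(EEG_BANDS)))
    rowSums(P[, i, drop = FALSE])
  }, numeric(n))
  tot <- rowSums(band_pow)
  tot[tot <= 0] <- NA_real_
  im <- band_bins(fr_eeg, c(1, 32), closed_upper = TRUE)
  mpf <- as.numeric(P[, im, drop = FALSE] %*% fr_eeg[im]) /
    rowSums(P[, im, drop = FALSE])
  ie <- band_bins(emg_spec$freqs, EMG_BAND, closed_upper = TRUE)
  tibble::tibble(
    epoch_index = seq_len(n),
    t_start_s = eeg_spec$times,
    mpf_hz = mpf,
    emg_power = rowSums(emg_spec$power[, ie, drop = FALSE]),
    delta_fr = band_pow[, 1] / tot, theta_fr = band_pow[, 2] / tot,
    alpha_fr = band_pow[, 3] / tot, beta_fr = band_pow[, 4] / tot
  )
}

#' Write a per-epoch feature table to CSV
#'
#' @param features Tibble from [epoch_features()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
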
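#' Detect R peaks in an ECG trace
#'
#' A Pan-Tompkins-style detector: the trace is band-passed (5-40 Hz,
#' zero-phase Butterworth), squared, and integrated over a 150 ms moving
#' window; local maxima of the integrated signal are accepted against an
#' adaptive threshold (running signal-level estimate) with a 60 ms
#' refractory period, and each accepted peak is refined to the local
#' maximum of the raw trace within +/- 40 ms.
#'
#' @param ecg Numeric ECG trace.
#' @param fs Sampling rate in Hz (500 for this acquisition setup).
#' @return Beat times in seconds (possibly empty, with a warning, if no
#'   peaks rise above threshold).
#' @export
detect_r_peaks <- function(ecg, fs = FS_ECG) {
  if (length(ecg) < 10 * fs) stop("need at least 10 s of ECG", call. = FALSE)
  f <- zerophase_bandpass(ecg, fs, c(5, 40), order = 2)
  sq <- f^2
  nw <- round(0.150 * fs)
  half0 <- nw %/% 2
  n <- length(sq)
  cs <- cumsum(c(0, sq))
  idx <- seq_len(n)
  lo <- pmax(idx - half0, 1L)
  hi <- pmin(idx + half0, n)
  mwi <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)

  top <- quantile(mwi, 0.99)
  if (top <= 0) {
    warning("no peaks above threshold; flat signal?", call. = FALSE)
    return(numeric(0))
  }

  # One detection per contiguous above-threshold region of the integrated
  # signal (up-crossing to down-crossing), so the wide integration plateau
  # of a single QRS cannot fire twice; the threshold adapts to a running
  # signal-level estimate.
  refract <- round(0.060 * fs)
  spk <- top
  thr <- 0.3 * spk
  above <- mwi > thr
  edges_up <- which(diff(c(FALSE, above)) == 1)
  edges_dn <- which(diff(c(above, FALSE)) == -1)
  # argmax of mwi within each region, vectorized over regions
  reg_len <- edges_dn - edges_up + 1L
  reg_id <- rep.int(seq_along(edges_up), reg_len)
  pos <- sequence(reg_len) + rep.int(edges_up, reg_len) - 1L
  ord <- order(reg_id, -mwi[pos])
  cand <- pos[ord][!duplicated(reg_id[ord])]

  peaks <- integer(length(cand))
  np <- 0L
  last <- -Inf
  for (i in cand) {
    if (mwi[i] > thr && (i - last) > refract) {
      np <- np + 1L
      peaks[np] <- i
      last <- i
      spk <- 0.125 * mwi[i] + 0.875 * spk
      thr <- 0.3 * spk
    }
  }
  peaks <- peaks[seq_len(np)]
  if (length(peaks) == 0) {
    warning("no peaks above threshold", call. = FALSE)
    return(numeric(0))
  }
  # refine to the raw-trace local maximum within +/- 40 ms; a short (10 ms)
  # moving average suppresses sample-level noise around the flat QRS apex
  half <- round(0.040 * fs)
  nsm <- max(1L, round(0.010 * fs))
  css <- cumsum(c(0, ecg))
  idx2 <- seq_along(ecg)
  slo <- pmax(idx2 - nsm %/% 2, 1L)
  shi <- pmin(idx2 + nsm %/% 2, length(ecg))
  smoothed <- (css[shi + 1] - css[slo]) / (shi - slo + 1)
  lo <- pmax(1L, peaks - half)
  hi <- pmin(length(ecg), peaks + half)
  refined <- vapply(seq_along(peaks), function(k) {
    as.integer(lo[k] + which.max(smoothed[lo[k]:hi[k]]) - 1L)
  }, integer(1))
  sort(unique(refined - 1L)) / fs
}

#' Build an artifact-masked RR tachogram
#'
#' Converts beat times to RR intervals (ms) and masks implausible ones:
#' intervals outside the physiologic bounds, or deviating more than 30%
#' from the running median of the surrounding 9 intervals (ectopy / missed-
#' or false-beat guard).
#'
#' @param beat_times Beat times in seconds, strictly increasing.
#' @param bounds Physiologic RR bounds in ms (rat default 100-350 ms).
#' @return A tibble with `t_s` (time of the beat closing each interval),
#'   `rr_ms`, and `artifact` (TRUE = masked).
#' @export
rr_tachogram <- function(beat_times, bounds = c(100, 350)) {
  if (length(beat_times) < 2) stop("need at least 2 beats", call. = FALSE)
  rr <- diff(beat_times) * 1000
  med <- if (length(rr) >= 9) stats::runmed(rr, 9) else rep(median(rr),
                                                            length(rr))
  artifact <- rr < bounds[1] | rr > bounds[2] | abs(rr - med) > 0.30 * med
  if (all(artifact)) {
    warning("all RR intervals masked as artifacts", call. = FALSE)
  }
  tibble::tibble(t_s = beat_times[-1], rr_ms = rr, artifact = artifact)
}

#' Resample the RR tachogram onto a uniform grid
#'
#' Cubic-spline interpolation of the unmasked tachogram (RR value anchored
#' at the beat closing each interval) evaluated on a uniform grid (default
#' 64 Hz) spanning the first to the last retained beat; masked intervals
#' are bridged by the interpolant.
#'
#' @param tacho Tibble from [rr_tachogram()].
#' @param rate Resampling rate in Hz.
#' @return A list with `t` (grid times, s), `rr` (ms) and `fs`.
#' @export
resample_rr <- function(tacho, rate = 64) {
  keep <- !tacho$artifact
  if (sum(keep) < 2) stop("need at least 2 unmasked intervals", call. = FALSE)
  x <- tacho$t_s[keep]
  y <- tacho$rr_ms[keep]
  if (diff(range(x)) < 16) {
    stop("tachogram span below 16 s; no full segment possible", call. = FALSE)
  }
  sf <- splinefun(x, y, method = "natural")
  t <- seq(x[1], x[length(x)], by = 1 / rate)
  list(t = t, rr = sf(t), fs = rate)
}

#' Spectral LF/HF powers of the uniform RR series
#'
#' Truncates the uniform series into 16 s segments (1024 points at 64 Hz)
#' with 50% overlap; each segment is mean-removed, Hamming-tapered and
#' Fourier-transformed (1/16 Hz resolution). LF power is the summed
#' spectral power over \[0.06, 0.6) Hz and HF over \[0.6, 2.4\] Hz — the
#' rat-specific sympathetic and vagal modulation bands; the shared 0.6 Hz
#' boundary belongs to HF.
#'
#' @param uniform List from [resample_rr()].
#' @param nfft Segment length in samples.
#' @return A tibble of segments: `t_start_s`, `mean_rr_ms`, `lf_ms2`,
#'   `hf_ms2`.
#' @export
hrv_spectra <- function(uniform, nfft = 1024) {
  n <- length(uniform$rr)
  if (n < nfft) stop("series shorter than one segment", call. = FALSE)
  hop <- nfft %/% 2
  n_seg <- (n - nfft) %/% hop + 1L
  rows <- purrr::map(seq_len(n_seg), function(k) {
    i0 <- (k - 1L) * hop
    seg <- uniform$rr[(i0 + 1):(i0 + nfft)]
    sp <- hamming_periodogram(seg, uniform$fs)
    tibble::tibble(
      t_start_s = uniform$t[i0 + 1],
      mean_rr_ms = mean(seg),
      lf_ms2 = sum(sp$power[band_bins(sp$freq, LF_BAND)]),
      hf_ms2 = sum(sp$power[band_bins(sp$freq, HF_BAND,
                                      closed_upper = TRUE)])
    )
  })
  dplyr::bind_rows(rows)
}

#' Stage-conditioned HRV summary
#'
#' Assigns each 16 s HRV segment a sleep stage — by default only when every
#' 8 s epoch the segment overlaps carries the same non-ERR label
#' (conservative; `rule = "majority"` takes the modal label instead) — and
#' summarizes RR and the log-transformed band powers overall and per stage.
#' By default the natural log is applied to the per-stage mean band power
#' (`log_order = "log_of_mean"`; `"mean_of_logs"` averages per-segment
#' logs instead). The log LF/HF ratio is `log_lf - log_hf` by construction.
#' Stages with no assigned segments are absent from the output, not zero.
#'
#' @param segments Tibble from [hrv_spectra()].
#' @param labeled Per-epoch labels: a tibble with a `label` column (from
#'   [classify_epochs()]) or a character vector.
#' @param epoch_len_s Epoch length in seconds.
#' @param rule Segment-to-stage assignment: `"all"` or `"majority"`.
#' @param log_order `"log_of_mean"` or `"mean_of_logs"`.
#' @param window_s Segment length in seconds.
#' @return A tibble of class `somnark_stagehrv`: one row per stratum
#'   (`overall` plus each stage present) with `n_segments`, `mean_rr_ms`,
#'   `log_lf`, `log_hf`, `log_lfhf`.
#' @export
stage_conditioned_hrv <- function(segments, labeled, epoch_len_s = 8,
                                  rule = c("all", "majority"),
                                  log_order = c("log_of_mean",
                                                "mean_of_logs"),
                                  window_s = 16) {
  rule <- match.arg(rule)
  log_order <- match.arg(log_order)
  lab <- as.character(if (is.data.frame(labeled)) labeled$label else labeled)

  assign_stage <- function(t0) {
    e0 <- floor(t0 / epoch_len_s) + 1
    e1 <- floor((t0 + window_s - 1e-9) / epoch_len_s) + 1
    if (e0 < 1 || e1 > length(lab)) return(NA_character_)
    covered <- lab[e0:e1]
    if (rule == "all") {
      if (length(unique(covered)) == 1 && covered[1] != "ERR") covered[1]
      else NA_character_
    } else {
      covered <- covered[covered != "ERR"]
      if (length(covered) == 0) return(NA_character_)
      names(sort(table(covered), decreasing = TRUE))[1]
    }
  }
  segments$stage <- vapply(segments$t_start_s, assign_stage, character(1))

  summarize_stratum <- function(df, name) {
    if (nrow(df) == 0) return(NULL)
    if (log_order == "log_of_mean") {
      log_lf <- log(mean(df$lf_ms2))
      log_hf <- log(mean(df$hf_ms2))
    } else {
      log_lf <- mean(log(df$lf_ms2))
      log_hf <- mean(log(df$hf_ms2))
    }
    tibble::tibble(stratum = name, n_segments = nrow(df),
                   mean_rr_ms = mean(df$mean_rr_ms),
                   log_lf = log_lf, log_hf = log_hf,
                   log_lfhf = log_lf - log_hf)
  }
  out <- dplyr::bind_rows(
    summarize_stratum(segments, "overall"),
    purrr::map(STAGES, function(s) {
      summarize_stratum(segments[!is.na(segments$stage) &
                                   segments$stage == s, ], s)
    })
  )
  class(out) <- c("somnark_stagehrv", class(out))
  attr(out, "segments") <- segments
  out
}

#' Write HRV segment and stage-summary tables to CSV
#'
#' @param stagehrv Result of [stage_conditioned_hrv()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_hrv_csv <- function(stagehrv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "hrv_segments.csv")
  seg <- attr(stagehrv, "segments")
  write.csv(seg, p1, row.names = FALSE)
  p2 <- file.path(dir, "hrv_stage_summary.csv")
  write.csv(as.data.frame(stagehrv), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
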
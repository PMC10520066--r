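unmodulated_ecg <- function(minutes = 2, mean_rr = 200, seed = 1) {
  cfg <- sim_config(rr_lf_amp = c(AW = 0, QS = 0, PS = 0),
                    rr_hf_amp = c(AW = 0, QS = 0, PS = 0),
                    rr_noise_sd = 0, mean_rr = mean_rr)
  synthesize_ecg(rep("QS", minutes * 60 / 8), cfg, seed = seed)
}

test_that("R-peak detection recovers clean and noisy beat trains", {
  e <- unmodulated_ecg(2)
  beats <- detect_r_peaks(e$trace)
  expect_lt(max(abs(diff(beats) * 1000 - 200)), 2)

  # 20 dB SNR (noise power 1% of signal power): >= 99% of true beats
  # matched within one sample
  set.seed(41)
  noise_sd <- sqrt(mean(e$trace^2) / 100)
  noisy <- e$trace + rnorm(length(e$trace), sd = noise_sd)
  bn <- detect_r_peaks(noisy)
  nearest <- vapply(e$beat_times, function(t) min(abs(bn - t)), numeric(1))
  expect_gte(mean(nearest <= 1 / 500 + 1e-9), 0.99)

  expect_warning(z <- detect_r_peaks(numeric(500 * 12)), "threshold")
  expect_length(z, 0)
  expect_error(detect_r_peaks(numeric(100)), "10 s")
})

test_that("tachogram masking flags dropouts and implausible intervals", {
  e <- unmodulated_ecg(2)
  tac <- rr_tachogram(e$beat_times)
  expect_identical(sum(tac$artifact), 0L)

  # one dropped beat: exactly the resulting 400 ms interval is masked
  drop <- e$beat_times[-100]
  tac2 <- rr_tachogram(drop)
  expect_identical(sum(tac2$artifact), 1L)
  expect_equal(tac2$rr_ms[tac2$artifact], 400, tolerance = 0.01)

  # bounds violated everywhere
  expect_warning(tac3 <- rr_tachogram(seq(0, 60, by = 0.5)), "masked")
  expect_true(all(tac3$artifact))

  expect_error(rr_tachogram(1), "2 beats")
})

test_that("RR resampling interpolates onto a uniform 64 Hz grid", {
  const <- tibble::tibble(t_s = seq(0.2, 60, by = 0.2),
                          rr_ms = 200, artifact = FALSE)
  u <- resample_rr(const)
  expect_equal(u$fs, 64)
  expect_lt(max(abs(u$rr - 200)), 1e-9)

  ramp <- tibble::tibble(t_s = seq(0.2, 60.2, by = 0.2))
  ramp$rr_ms <- 180 + (ramp$t_s - 0.2) / 60 * 40
  ramp$artifact <- FALSE
  ur <- resample_rr(ramp)
  expected <- 180 + (ur$t - 0.2) / 60 * 40
  interior <- ur$t > 2 & ur$t < 58
  expect_lt(max(abs(ur$rr - expected)[interior]), 0.5)

  span <- tibble::tibble(t_s = seq(0.2, 120.2, by = 0.2), rr_ms = 200,
                         artifact = FALSE)
  expect_true(abs(length(resample_rr(span)$rr) - 120 * 64) <= 1)

  short <- tibble::tibble(t_s = c(0, 10), rr_ms = 200, artifact = FALSE)
  expect_error(resample_rr(short), "16 s")
})

test_that("segment spectra place sinusoidal RR power in the right band", {
  t <- seq(0, 600, by = 1 / 64)
  mk <- function(f, a = 10) list(t = t, rr = 200 + a * sin(2 * pi * f * t),
                                 fs = 64)
  seg_const <- hrv_spectra(list(t = t, rr = rep(200, length(t)), fs = 64))
  expect_lt(max(seg_const$lf_ms2), 1e-6)
  expect_lt(max(seg_const$hf_ms2), 1e-6)
  expect_equal(mean(seg_const$mean_rr_ms), 200)

  hf <- hrv_spectra(mk(1.2))
  expect_lt(abs(mean(hf$hf_ms2) - 50) / 50, 0.15) # A^2/2 = 50 ms^2
  expect_gt(mean(hf$hf_ms2), 10 * mean(hf$lf_ms2))

  lf <- hrv_spectra(mk(0.3))
  expect_lt(abs(mean(lf$lf_ms2) - 50) / 50, 0.15)
  expect_gt(mean(lf$lf_ms2), 10 * mean(lf$hf_ms2))

  expect_error(hrv_spectra(list(t = t[1:100], rr = rep(200, 100), fs = 64)),
               "shorter")
})

test_that("segment power is additive (Parseval) on the uniform series", {
  set.seed(42)
  rr <- 200 + as.numeric(arima.sim(list(ar = 0.9), 1024, sd = 1))
  sp <- sliding_spectrum(rr, 64)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:1023) / 1023)
  tapered_var <- sum(((rr - mean(rr)) * w)^2) / sum(w^2)
  expect_equal(sum(sp$power[1, ]), tapered_var, tolerance = 1e-3)
})

test_that("stage conditioning assigns segments conservatively", {
  seg <- tibble::tibble(
    t_start_s = c(0, 8, 16, 24),
    mean_rr_ms = 200,
    lf_ms2 = exp(2.41), hf_ms2 = exp(1.51)
  )
  lab <- c("QS", "QS", "QS", "AW", "QS") # epochs of 8 s
  sh <- stage_conditioned_hrv(seg, lab)
  # segments 0-16 and 8-24 lie fully in QS; 16-32 and 24-40 straddle the AW
  # epoch and stay unassigned under the conservative rule
  expect_identical(sh$n_segments[sh$stratum == "QS"], 2L)
  expect_false("AW" %in% sh$stratum)
  # the published log arithmetic: LF/HF in log units is log LF - log HF
  qs <- sh[sh$stratum == "QS", ]
  expect_equal(qs$log_lf, 2.41)
  expect_equal(qs$log_hf, 1.51)
  expect_equal(qs$log_lfhf, 0.90)
  expect_identical(sh$log_lfhf, sh$log_lf - sh$log_hf)

  # all-ERR labels: per-stage strata absent, overall still computed
  sh2 <- stage_conditioned_hrv(seg, rep("ERR", 5))
  expect_identical(sh2$stratum, "overall")

  # majority rule assigns at least as many segments as the conservative one
  sh3 <- stage_conditioned_hrv(seg, lab, rule = "majority")
  expect_gte(sum(sh3$n_segments[sh3$stratum != "overall"]),
             sum(sh$n_segments[sh$stratum != "overall"]))
})

test_that("shuffling stage labels destroys a configured LF/HF contrast", {
  res <- res30()
  sh <- res$stage_hrv
  d_orig <- sh$log_lfhf[sh$stratum == "AW"] - sh$log_lfhf[sh$stratum == "QS"]
  lab <- as.character(res$labeled$label)
  set.seed(43)
  d_shuf <- replicate(5, {
    shuffled <- sample(lab)
    s <- stage_conditioned_hrv(res$hrv_segments, shuffled)
    a <- s$log_lfhf[s$stratum == "AW"]
    q <- s$log_lfhf[s$stratum == "QS"]
    if (length(a) && length(q)) a - q else NA_real_
  })
  expect_lt(mean(abs(d_shuf), na.rm = TRUE), abs(d_orig))
})
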
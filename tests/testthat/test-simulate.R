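test_that("degenerate all-QS configuration yields pure QS and no intrusions", {
  cfg <- sim_config(stage_mix = c(AW = 0, QS = 1, PS = 0),
                    qs_interruption_rate = 0, duration_min = 10)
  hyp <- simulate_stage_sequence(cfg, seed = 1)
  expect_true(all(hyp$labels == "QS"))
  expect_identical(nrow(hyp$injected), 0L)
  expect_identical(length(hyp$labels), 75L)
})

test_that("QS bout lengths are geometric at the configured mean", {
  # 10 000 epochs, no intrusions: empirical mean QS run length within 10%
  cfg <- sim_config(duration_min = 10000 * 8 / 60,
                    qs_interruption_rate = 0,
                    stage_mean_bouts = c(AW = 12, QS = 20, PS = 12))
  hyp <- simulate_stage_sequence(cfg, seed = 1)
  r <- rle(hyp$labels)
  qs_runs <- r$lengths[r$values == "QS"]
  expect_gt(mean(qs_runs), 18)
  expect_lt(mean(qs_runs), 22)
})

test_that("the stage sequence is reproducible per seed", {
  cfg <- sim_config(duration_min = 20)
  a <- simulate_stage_sequence(cfg, seed = 7)
  b <- simulate_stage_sequence(cfg, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$injected, b$injected)
  c <- simulate_stage_sequence(cfg, seed = 8)
  expect_false(identical(a$labels, c$labels))
})

test_that("stage fractions track the configured mix", {
  # expectation at 2 h, estimated over 6 replicate hypnograms
  cfg <- sim_config_control(duration_min = 120)
  frac <- sapply(1:6, function(s) {
    hyp <- simulate_stage_sequence(cfg, seed = s)
    table(factor(hyp$labels, c("AW", "QS", "PS"))) / length(hyp$labels)
  })
  avg <- 100 * rowMeans(frac)
  target <- 100 * cfg$stage_mix[c("AW", "QS", "PS")]
  expect_true(all(abs(avg - target) <= 5))
})

test_that("EEG band composition follows the per-stage weights", {
  # single-band config: essentially all power in delta
  cfg1 <- sim_config(eeg_band_weights = list(AW = c(1, 0, 0, 0),
                                             QS = c(1, 0, 0, 0),
                                             PS = c(1, 0, 0, 0)))
  x <- synthesize_eeg(rep("QS", 40), cfg1, seed = 1)
  sp <- sliding_spectrum(x, 125)
  fr <- band_power_fractions(colMeans(sp$power), sp$freqs)
  expect_gt(fr[["delta"]], 0.95)

  # mixed weights over 30 min: recovered fractions within +/- 0.05
  w <- c(0.85, 0.07, 0.03, 0.05)
  cfg2 <- sim_config(eeg_band_weights = list(AW = w, QS = w, PS = w))
  x2 <- synthesize_eeg(rep("QS", 225), cfg2, seed = 2)
  fr2 <- band_power_fractions(colMeans(sliding_spectrum(x2, 125)$power),
                              sliding_spectrum(x2, 125)$freqs)
  expect_true(all(abs(fr2 - w) <= 0.05))

  # length contract and label validation
  expect_length(x, 40 * 8 * 125)
  expect_error(synthesize_eeg(c("QS", "XX"), cfg1), "unknown stage")
})

test_that("EMG amplitude is stage-dependent with the configured contrast", {
  cfg <- sim_config(emg_gain = c(AW = 10, QS = 1, PS = 1))
  lab <- c(rep("AW", 30), rep("QS", 30))
  x <- synthesize_emg(lab, cfg, seed = 3)
  expect_length(x, 60 * 8 * 250)
  fs <- 250
  aw <- x[(2 * 8 * fs):(28 * 8 * fs)] # interiors, away from the cross-fade
  qs <- x[(32 * 8 * fs):(58 * 8 * fs)]
  ratio <- mean(aw^2) / mean(qs^2)
  expect_gt(ratio, 80)
  expect_lt(ratio, 120)

  z <- synthesize_emg(lab, sim_config(emg_gain = c(AW = 0, QS = 0, PS = 0)))
  expect_true(all(z == 0))
})

test_that("IPFM beat generation honours the instantaneous RR", {
  # unmodulated: all true intervals exactly mean_rr
  cfg0 <- sim_config(rr_lf_amp = c(AW = 0, QS = 0, PS = 0),
                     rr_hf_amp = c(AW = 0, QS = 0, PS = 0),
                     rr_noise_sd = 0, mean_rr = 200)
  e <- synthesize_ecg(rep("QS", 8), cfg0, seed = 1) # 64 s
  expect_lt(max(abs(diff(e$beat_times) - 0.2)), 1e-9)
  # rate arithmetic: ~300 beats in 60 s
  n60 <- sum(e$beat_times <= 60)
  expect_true(abs(n60 - 300) <= 2)

  # HF modulation at 1.2 Hz dominates the true tachogram spectrum
  cfgh <- sim_config(rr_lf_amp = c(AW = 0, QS = 0, PS = 0),
                     rr_hf_amp = c(AW = 10, QS = 10, PS = 10),
                     rr_noise_sd = 0, hf_mod_freq = 1.2)
  eh <- synthesize_ecg(rep("QS", 75), cfgh, seed = 2) # 10 min
  tac <- rr_tachogram(eh$beat_times)
  u <- resample_rr(tac)
  sp <- sliding_spectrum(u$rr, u$fs)
  pw <- colMeans(sp$power)
  peak <- sp$freqs[-1][which.max(pw[-1])] # skip DC
  expect_equal(peak, 1.2, tolerance = 1 / 16 / 1.2)
})

test_that("tachogram band power scales quadratically with modulation amplitude", {
  hf_est <- sapply(c(5, 10, 20), function(a) {
    cfg <- sim_config(rr_lf_amp = c(AW = 0, QS = 0, PS = 0),
                      rr_hf_amp = c(AW = a, QS = a, PS = a),
                      rr_noise_sd = 0, hf_mod_freq = 1.2)
    e <- synthesize_ecg(rep("QS", 45), cfg, seed = 4) # 6 min
    seg <- hrv_spectra(resample_rr(rr_tachogram(e$beat_times)))
    mean(seg$hf_ms2)
  })
  # power-law check: doubling the amplitude quadruples the band power
  # (absolute levels carry the known IPFM beat-sampling attenuation)
  expect_lt(abs(hf_est[2] / hf_est[1] - 4) / 4, 0.15)
  expect_lt(abs(hf_est[3] / hf_est[2] - 4) / 4, 0.15)
})

test_that("generate_recording bundles consistent, reproducible channels", {
  rec <- rec30()
  n_ep <- length(rec$truth$labels)
  expect_identical(n_ep, 225L)
  expect_length(rec$eeg, n_ep * 8 * 125)
  expect_length(rec$emg, n_ep * 8 * 250)
  expect_length(rec$ecg, n_ep * 8 * 500)
  expect_true(all(diff(rec$truth$beat_times) > 0))

  rec2 <- generate_recording(sim_config_control(30, seed = 0))
  expect_identical(rec2$eeg, rec$eeg)
  expect_identical(rec2$ecg, rec$ecg)
  expect_identical(rec2$truth$labels, rec$truth$labels)
})
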
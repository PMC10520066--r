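# Session-level fixture cache: expensive synthetic recordings and replicate
# simulations are built once and shared across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 30-min control recording and its pipeline result (the default
# well-separated staging round-trip fixture)
rec30 <- function() {
  fixture("rec30", generate_recording(sim_config_control(30, seed = 0)))
}

res30 <- function() {
  fixture("res30", suppressWarnings(run_pipeline(rec30())))
}

# Brute-force run-length oracle: maximal runs of identical non-ERR labels,
# built by a plain loop, independent of form_stages()
rle_oracle <- function(lab, min_run = 6) {
  bouts <- list()
  intr <- list()
  i <- 1L
  n <- length(lab)
  while (i <= n) {
    if (lab[i] == "ERR") {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && lab[j + 1] == lab[i]) j <- j + 1L
    run <- list(stage = lab[i], start = i, end = j, len = j - i + 1L)
    if (run$len >= min_run) bouts[[length(bouts) + 1]] <- run
    else intr[[length(intr) + 1]] <- run
    i <- j + 1L
  }
  list(bouts = bouts, interruptions = intr)
}

# Exact Mann-Whitney two-sided p by enumeration of all rank splits
mw_enum_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  rk <- rank(pool)
  splits <- utils::combn(length(pool), n)
  us <- apply(splits, 2, function(ix) sum(rk[ix]) - n * (n + 1) / 2)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Single-animal quiet-sleep HRV summary through the ECG chain only, staged
# against the ground-truth hypnogram (used for replicate simulations where
# the EEG/EMG staging chain is not under test)
qs_lfhf_hrv_only <- function(config, seed) {
  hyp <- simulate_stage_sequence(config, seed)
  ecg <- synthesize_ecg(hyp$labels, config, seed)
  tac <- rr_tachogram(detect_r_peaks(ecg$trace))
  seg <- hrv_spectra(resample_rr(tac))
  sh <- stage_conditioned_hrv(seg, hyp$labels)
  sh$log_lfhf[sh$stratum == "QS"][1]
}

# Two-preset cohort replicates (6 control vs 6 exposure-like animals per
# replicate, 40-min recordings, full pipeline); cached because both the
# directional and the power acceptance checks consume it
cohort_replicates <- function(n_rep = 20, n_animal = 6, duration = 50) {
  fixture("cohorts", {
    one <- function(cfgfun, seed) {
      rec <- generate_recording(cfgfun(duration, seed = seed))
      res <- suppressWarnings(run_pipeline(rec))
      qs <- res$stage_hrv[res$stage_hrv$stratum == "QS", ]
      tibble::tibble(
        interruption = res$architecture$interruption_rate,
        qs_interruption = res$architecture$qs_interruption_rate,
        lfhf_qs = if (nrow(qs)) qs$log_lfhf else NA_real_
      )
    }
    purrr::map_dfr(seq_len(n_rep), function(r) {
      base <- 30000L + r * 100L
      dplyr::bind_rows(
        purrr::map_dfr(seq_len(n_animal), function(a) {
          dplyr::mutate(one(sim_config_control, base + a),
                        replicate = r, group = "control", animal = a)
        }),
        purrr::map_dfr(seq_len(n_animal), function(a) {
          dplyr::mutate(one(sim_config_pm25, base + 50L + a),
                        replicate = r, group = "pm25", animal = a)
        })
      )
    })
  })
}
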
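test_that("between-class-variance split separates a bimodal mixture", {
  set.seed(21)
  x <- c(rnorm(1000, 3.0, 0.5), rnorm(1000, 7.0, 0.5))
  thr <- otsu_split(x)
  expect_gt(thr, 4.0)
  expect_lt(thr, 6.0)
  # misclassification against component origin below 2%
  origin <- rep(c("low", "high"), each = 1000)
  pred <- ifelse(x > thr, "high", "low")
  expect_lt(mean(pred != origin), 0.02)

  # agreement with a naive O(n^2) exhaustive-split oracle
  set.seed(22)
  y <- c(rnorm(40, 0), rnorm(40, 4))
  ys <- sort(y)
  bcv <- sapply(1:(length(ys) - 1), function(k) {
    a <- ys[1:k]
    b <- ys[(k + 1):length(ys)]
    length(a) * length(b) / length(ys)^2 * (mean(a) - mean(b))^2
  })
  k <- which.max(bcv)
  expect_equal(otsu_split(y), (ys[k] + ys[k + 1]) / 2)

  expect_error(otsu_split(rep(1, 10)), "distinct")
})

test_that("threshold estimation flags degenerate histograms", {
  ft <- tibble::tibble(
    epoch_index = 1:300, t_start_s = (0:299) * 8,
    mpf_hz = rep(3.5, 300), emg_power = rep(1, 300),
    delta_fr = 0.9, theta_fr = 0.05, alpha_fr = 0.03, beta_fr = 0.02
  )
  expect_warning(estimate_thresholds(ft), "unimodal")

  # a segment with no waking: all epochs classified at sleep-level EMG
  set.seed(23)
  ft2 <- tibble::tibble(
    epoch_index = 1:300, t_start_s = (0:299) * 8,
    mpf_hz = c(rnorm(150, 3.5, 0.3), rnorm(150, 7.7, 0.4)),
    emg_power = exp(rnorm(300, 0, 0.3)),
    delta_fr = rep(c(0.9, 0.2), each = 150),
    theta_fr = 0.05, alpha_fr = 0.03, beta_fr = 0.02
  )
  thr2 <- suppressWarnings(estimate_thresholds(ft2))
  lab2 <- classify_epochs(ft2, thr2)
  expect_identical(sum(lab2$label == "AW"), 0L)
  expect_identical(sum(lab2$label == "ERR"), 0L)

  expect_error(estimate_thresholds(ft[1:50, ]), "fewer than")
})

test_that("manual threshold overrides are applied and recorded", {
  set.seed(24)
  ft <- tibble::tibble(
    epoch_index = 1:300, t_start_s = (0:299) * 8,
    mpf_hz = c(rnorm(150, 3.5, 0.3), rnorm(150, 8.5, 0.5)),
    emg_power = exp(c(rnorm(150, 0, 0.3), rnorm(150, 4.6, 0.3))),
    delta_fr = 0.5, theta_fr = 0.3, alpha_fr = 0.1, beta_fr = 0.1
  )
  thr <- estimate_thresholds(ft, t_mpf = 6.0, t_emg = 12)
  expect_equal(thr$t_mpf, 6.0)
  expect_equal(thr$t_emg, 12)
  expect_identical(thr$source, "manual")
})

test_that("the four-way threshold rule is total and exclusive", {
  thr <- tibble::tibble(segment_id = 1L, t_start_s = 0, t_end_s = 8 * 4,
                        t_mpf = 5, t_emg = 10, bimod_mpf = 1, bimod_emg = 1,
                        source = "otsu")
  ft <- tibble::tibble(
    epoch_index = 1:4, t_start_s = (0:3) * 8,
    mpf_hz = c(7, 3, 7, 3), emg_power = c(20, 2, 2, 20),
    delta_fr = 0.25, theta_fr = 0.25, alpha_fr = 0.25, beta_fr = 0.25
  )
  lab <- classify_epochs(ft, thr)
  expect_identical(as.character(lab$label), c("AW", "QS", "PS", "ERR"))

  # boundary: "above" strict, "below" non-strict
  ftb <- dplyr::mutate(ft, mpf_hz = 5, emg_power = 10)
  expect_true(all(classify_epochs(ftb, thr)$label == "QS"))

  # missing features are ERR
  ftn <- dplyr::mutate(ft, mpf_hz = c(NA, 3, 7, 3))
  expect_identical(as.character(classify_epochs(ftn, thr)$label)[1], "ERR")
})

test_that("bout formation follows the minimum-run rule", {
  st1 <- form_stages(rep("QS", 6))
  expect_identical(nrow(st1$bouts), 1L)
  expect_identical(nrow(st1$interruptions), 0L)

  st2 <- form_stages(c(rep("QS", 10), rep("AW", 3), rep("QS", 10)))
  expect_identical(nrow(st2$bouts), 2L)
  expect_identical(nrow(st2$interruptions), 1L)
  expect_identical(st2$interruptions$stage, "AW")

  st3 <- form_stages(rep(c("QS", "AW"), 20))
  expect_identical(nrow(st3$bouts), 0L)
  expect_identical(nrow(st3$interruptions), 40L)

  empty <- form_stages(character(0))
  expect_identical(nrow(empty$bouts), 0L)
})

test_that("bouts and interruptions match a brute-force run-length oracle", {
  set.seed(31)
  for (i in 1:1000) {
    lab <- sample(c("AW", "QS", "PS", "ERR"), sample(5:60, 1),
                  replace = TRUE, prob = c(0.3, 0.35, 0.25, 0.1))
    st <- form_stages(lab)
    or <- rle_oracle(lab)
    expect_identical(nrow(st$bouts), length(or$bouts))
    expect_identical(nrow(st$interruptions), length(or$interruptions))
    if (length(or$interruptions)) {
      expect_identical(st$interruptions$start_epoch,
                       vapply(or$interruptions, `[[`, 1L, "start"))
    }
    # partition: every non-ERR epoch in exactly one bout or interruption
    covered <- sum(st$bouts$n_epochs) + sum(st$interruptions$n_epochs)
    expect_identical(covered, sum(lab != "ERR"))
  }
})

test_that("adding intrusions never decreases the interruption count", {
  set.seed(32)
  for (i in 1:50) {
    lab <- rep("QS", 120)
    n0 <- nrow(form_stages(lab)$interruptions)
    # inject 1-5 epoch AW runs strictly inside current QS stretches,
    # cumulatively
    for (j in 1:6) {
      len <- sample(1:5, 1)
      ok <- which(vapply(2:(120 - len), function(s) {
        all(lab[(s - 1):(s + len)] == "QS")
      }, logical(1))) + 1L
      if (length(ok) == 0) break
      start <- if (length(ok) == 1) ok else sample(ok, 1)
      lab[start:(start + len - 1)] <- "AW"
      n1 <- nrow(form_stages(lab)$interruptions)
      expect_gte(n1, n0)
      n0 <- n1
    }
  }
})

test_that("architecture metrics summarize time, bouts and transitions", {
  mk <- function(lab) {
    tibble::tibble(
      epoch_index = seq_along(lab), t_start_s = (seq_along(lab) - 1) * 8,
      mpf_hz = 3, emg_power = 1, delta_fr = 0.88, theta_fr = 0.07,
      alpha_fr = 0.03, beta_fr = 0.02, label = factor(lab, c("AW", "QS",
                                                             "PS", "ERR"))
    )
  }
  # constant 10-min series
  lab <- rep("QS", 75)
  arch <- architecture_metrics(mk(lab), form_stages(lab))
  expect_equal(arch$time_pct[["QS"]], 100)
  expect_equal(arch$interruption_rate, 0)
  expect_true(all(arch$transitions == 0))
  expect_equal(unname(arch$qs_band_pct["delta"]), 88)

  # 3 interruption events in 10 valid minutes -> 0.3 events/min
  lab2 <- rep("QS", 75)
  for (s in c(10, 30, 50)) lab2[s:(s + 1)] <- "AW"
  arch2 <- architecture_metrics(mk(lab2), form_stages(lab2))
  expect_equal(arch2$interruption_rate, 3 / 10)
  expect_equal(arch2$qs_interruption_rate, 3 / (69 * 8 / 60))

  # bout sequence AW, QS, PS, QS
  lab3 <- c(rep("AW", 6), rep("QS", 6), rep("PS", 6), rep("QS", 6))
  arch3 <- architecture_metrics(mk(lab3), form_stages(lab3))
  expect_identical(unname(arch3$transitions[c("A-Q", "Q-P", "P-Q")]),
                   c(1L, 1L, 1L))
  expect_identical(sum(arch3$transitions), 3L)

  expect_error(architecture_metrics(mk(rep("ERR", 10)),
                                    form_stages(rep("ERR", 10))),
               "no valid")
})

test_that("recovery report scores predictions against ground truth", {
  truth <- rep(c("AW", "QS", "PS"), length.out = 100)
  expect_equal(staging_recovery_report(truth, truth)$accuracy, 1)
  flip <- truth
  flip[1] <- "QS"
  expect_equal(staging_recovery_report(flip, truth)$accuracy, 0.99)
  expect_error(staging_recovery_report(truth[1:50], truth), "length")
})
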
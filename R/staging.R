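#' One-dimensional between-class-variance-maximizing split
#'
#' The histogram-free analogue of Otsu's method: among all splits of the
#' sorted sample, pick the one maximizing the between-class variance
#' `w1 w2 (m1 - m2)^2`; the threshold is the midpoint between the two
#' samples that straddle the best split. Used to separate the two
#' populations (e.g. AW/PS-complex vs QS on MPF) in a feature histogram.
#'
#' @param x Numeric sample (at least two distinct values).
#' @return The threshold (numeric scalar).
#' @export
otsu_split <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2 || x[1] == x[n]) stop("need at least two distinct values",
                                  call. = FALSE)
  cs <- cumsum(x)
  i <- seq_len(n - 1)
  w1 <- i / n
  m1 <- cs[i] / i
  m2 <- (cs[n] - cs[i]) / (n - i)
  bcv <- w1 * (1 - w1) * (m1 - m2)^2
  k <- which.max(bcv)
  (x[k] + x[k + 1]) / 2
}

# Sarle's bimodality coefficient: (skew^2 + 1) / adjusted kurtosis.
# Values above 5/9 are consistent with bimodality; used only as a
# diagnostic for flagging unimodal (unsplittable) segments.
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(NA_real_)
  z <- (x - mean(x)) / sd(x)
  g1 <- (n / ((n - 1) * (n - 2))) * sum(z^3)
  g2 <- ((n * (n + 1)) / ((n - 1) * (n - 2) * (n - 3))) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Estimate staging thresholds per 5-hour segment
#'
#' Cuts the feature series into segments (default 5 h), and within each
#' derives the MPF threshold from the MPF histogram and the EMG threshold
#' from the log-EMG-power histogram, both by the between-class-variance
#' split ([otsu_split()]). A final partial segment shorter than
#' `min_segment_min` reuses the previous segment's thresholds. A segment
#' whose histogram looks unimodal (bimodality coefficient below 5/9) is
#' flagged with a warning. Manual overrides replace the automatic values
#' and are recorded in the `source` column.
#'
#' @param features Epoch feature tibble from [epoch_features()].
#' @param segment_len_h Segment length in hours.
#' @param min_segment_min Minimum length (minutes) for a segment to get its
#'   own thresholds.
#' @param t_mpf,t_emg Optional manual overrides (applied to all segments).
#' @param epoch_len_s Epoch length in seconds.
#' @return A tibble with one row per segment: `segment_id`, `t_start_s`,
#'   `t_end_s`, `t_mpf`, `t_emg`, `bimod_mpf`, `bimod_emg`, `source`.
#' @export
estimate_thresholds <- function(features, segment_len_h = 5,
                                min_segment_min = 30,
                                t_mpf = NULL, t_emg = NULL,
                                epoch_len_s = 8) {
  seg_len_s <- segment_len_h * 3600
  seg_id <- features$t_start_s %/% seg_len_s + 1L
  ids <- sort(unique(seg_id))
  # one epoch of slack: the trailing epoch has no full feature window
  min_epochs <- ceiling(min_segment_min * 60 / epoch_len_s) - 1L

  res <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    f <- features[seg_id == ids[j], ]
    is_final_partial <- (j == length(ids)) && j > 1 && nrow(f) < min_epochs
    if (nrow(f) < min_epochs && !is_final_partial) {
      stop("segment ", ids[j], " has fewer than ", min_segment_min,
           " minutes of epochs", call. = FALSE)
    }
    if (is_final_partial) {
      prev <- res[[j - 1]]
      res[[j]] <- dplyr::mutate(prev, segment_id = ids[j],
                                t_start_s = (ids[j] - 1) * seg_len_s,
                                t_end_s = max(f$t_start_s) + epoch_len_s,
                                source = "carried_forward")
      next
    }
    bm_mpf <- bimodality_coefficient(f$mpf_hz)
    bm_emg <- bimodality_coefficient(log(f$emg_power))
    manual <- !is.null(t_mpf) || !is.null(t_emg)

    # class-mean gap guards: a "split" whose two classes sit closer than the
    # physiologic contrast (waking EMG exceeds sleep EMG by orders of
    # magnitude; the AW/PS MPF complex sits well above QS) is a split within
    # a single population, so the threshold is placed outside the histogram
    # instead
    split_gap <- function(x, thr) {
      mean(x[x > thr]) - mean(x[x <= thr])
    }
    unimodal <- FALSE

    tm <- t_mpf
    if (is.null(tm)) {
      if (sd(f$mpf_hz) == 0) {
        unimodal <- TRUE
        tm <- f$mpf_hz[1] + 1
      } else {
        tm <- otsu_split(f$mpf_hz)
        if (split_gap(f$mpf_hz, tm) < 1.5) {
          unimodal <- TRUE
          # single population: delta-dominant means it is QS (all below);
          # otherwise it is the AW/PS complex (all above)
          tm <- if (mean(f$delta_fr, na.rm = TRUE) > 0.5) {
            max(f$mpf_hz) + 1
          } else {
            min(f$mpf_hz) - 1
          }
        }
      }
    }
    te <- t_emg
    if (is.null(te)) {
      le <- log(f$emg_power)
      if (sd(le) == 0) {
        unimodal <- TRUE
        te <- exp(le[1] + 1)
      } else {
        lt <- otsu_split(le)
        if (split_gap(le, lt) < 1.5) {
          unimodal <- TRUE
          # no high-EMG (waking) population in this segment: every epoch is
          # at sleep-level EMG
          te <- exp(max(le) + 1)
        } else {
          te <- exp(lt)
        }
      }
    }
    if (!manual && (unimodal || is.na(bm_mpf) || bm_mpf < 5 / 9 ||
                    is.na(bm_emg) || bm_emg < 5 / 9)) {
      warning("segment ", ids[j],
              ": feature histogram looks unimodal; thresholds may be ",
              "unreliable (consider a manual override)", call. = FALSE)
    }
    res[[j]] <- tibble::tibble(
      segment_id = ids[j],
      t_start_s = (ids[j] - 1) * seg_len_s,
      t_end_s = min(ids[j] * seg_len_s, max(f$t_start_s) + epoch_len_s),
      t_mpf = tm, t_emg = te,
      bimod_mpf = bm_mpf, bimod_emg = bm_emg,
      source = if (manual) "manual" else "otsu"
    )
  }
  dplyr::bind_rows(res)
}

#' Classify epochs into AW / QS / PS / ERR
#'
#' The four-way threshold rule: MPF above the MPF threshold and EMG power
#' above the EMG threshold is active waking (AW); both below is quiet sleep
#' (QS); MPF above with EMG below is paradoxical sleep (PS); MPF below with
#' EMG above is physiologically implausible and marked erroneous (ERR),
#' excluded from all downstream rates. "Above" is strict (>), "below"
#' non-strict. Epochs with missing features are ERR.
#'
#' @param features Epoch feature tibble from [epoch_features()].
#' @param thresholds Tibble from [estimate_thresholds()].
#' @return The feature tibble with `label` (factor AW/QS/PS/ERR) and the
#'   applied `t_mpf`, `t_emg` columns appended.
#' @export
classify_epochs <- function(features, thresholds) {
  seg <- findInterval(features$t_start_s, thresholds$t_start_s)
  if (any(seg < 1 | seg > nrow(thresholds))) {
    stop("no thresholds available for some epochs", call. = FALSE)
  }
  tm <- thresholds$t_mpf[seg]
  te <- thresholds$t_emg[seg]
  mpf <- features$mpf_hz
  emg <- features$emg_power
  lab <- dplyr::case_when(
    !is.finite(mpf) | !is.finite(emg) ~ "ERR",
    mpf > tm & emg > te ~ "AW",
    mpf <= tm & emg <= te ~ "QS",
    mpf > tm & emg <= te ~ "PS",
    TRUE ~ "ERR"
  )
  dplyr::mutate(features,
                label = factor(lab, levels = c(STAGES, "ERR")),
                t_mpf = tm, t_emg = te)
}

#' Form bouts and interruption events from epoch labels
#'
#' A sleep-wake stage (bout) is a maximal run of at least `min_run`
#' consecutive identical non-ERR epochs; a shorter run is an interruption
#' event (one event per run). ERR epochs split runs and belong to neither.
#'
#' @param labels Character/factor vector of per-epoch labels, or a tibble
#'   with a `label` column.
#' @param min_run Minimum run length (epochs) for a bout.
#' @param epoch_len_s Epoch length in seconds.
#' @return A list with tibbles `bouts` and `interruptions`, each with
#'   `stage`, `start_epoch`, `end_epoch`, `n_epochs`, `start_s`, `end_s`.
#' @export
form_stages <- function(labels, min_run = 6, epoch_len_s = 8) {
  lab <- as.character(if (is.data.frame(labels)) labels$label else labels)
  empty <- tibble::tibble(stage = character(), start_epoch = integer(),
                          end_epoch = integer(), n_epochs = integer(),
                          start_s = numeric(), end_s = numeric())
  if (length(lab) == 0) return(list(bouts = empty, interruptions = empty))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  runs <- tibble::tibble(
    stage = r$values,
    start_epoch = ends - r$lengths + 1L,
    end_epoch = as.integer(ends),
    n_epochs = as.integer(r$lengths)
  ) |>
    dplyr::filter(.data$stage != "ERR") |>
    dplyr::mutate(start_s = (.data$start_epoch - 1) * epoch_len_s,
                  end_s = .data$end_epoch * epoch_len_s)
  list(
    bouts = dplyr::filter(runs, .data$n_epochs >= min_run),
    interruptions = dplyr::filter(runs, .data$n_epochs < min_run)
  )
}

#' Sleep architecture metrics
#'
#' Summarizes a labeled series into: percent time per stage (over valid,
#' i.e. non-ERR, epochs); mean bout duration per stage (s); the interruption
#' rate (interruption events per valid minute); the quiet-sleep interruption
#' rate (brief awakenings: short AW intrusions flanked by QS on both sides,
#' per minute of QS) — the fragmentation measure tied to deep-sleep
#' disturbance; the six
#' ordered stage-transition counts between consecutive bouts (interruption
#' runs skipped); and the mean delta/theta/alpha/beta EEG fractions over QS
#' epochs in normalized units (percent).
#'
#' @param labeled Tibble from [classify_epochs()] (needs `label` and the
#'   band-fraction columns).
#' @param staged List from [form_stages()] on the same labels.
#' @param epoch_len_s Epoch length in seconds.
#' @return An object of class `somnark_architecture` (a list); see
#'   [tidy.somnark_architecture()] for a tabular view.
#' @export
architecture_metrics <- function(labeled, staged, epoch_len_s = 8) {
  lab <- as.character(labeled$label)
  valid <- lab != "ERR"
  n_valid <- sum(valid)
  if (n_valid == 0) stop("no valid (non-ERR) epochs", call. = FALSE)
  valid_min <- n_valid * epoch_len_s / 60

  time_pct <- vapply(STAGES, function(s) 100 * sum(lab == s) / n_valid,
                     numeric(1))
  mean_bout_s <- vapply(STAGES, function(s) {
    b <- staged$bouts[staged$bouts$stage == s, ]
    if (nrow(b) == 0) NA_real_ else mean(b$n_epochs) * epoch_len_s
  }, numeric(1))

  interruption_rate <- nrow(staged$interruptions) / valid_min

  # QS-specific variant: brief awakenings from quiet sleep — short AW runs
  # whose nearest non-ERR neighbor on each side is QS (ERR epochs, e.g. from
  # window smearing at the intrusion edge, are skipped when looking for the
  # flanking stage). Short PS runs inside QS are ordinary QS-PS transition
  # attempts, not arousals, and are not counted here.
  qs_min <- sum(lab == "QS") * epoch_len_s / 60
  intr <- staged$interruptions
  neighbor <- function(i, step) {
    while (i >= 1 && i <= length(lab) && lab[i] == "ERR") i <- i + step
    if (i >= 1 && i <= length(lab)) lab[i] else NA_character_
  }
  flanked <- intr$stage == "AW" &
    vapply(intr$start_epoch - 1L, neighbor, character(1), step = -1L) %in%
      "QS" &
    vapply(intr$end_epoch + 1L, neighbor, character(1), step = 1L) %in% "QS"
  qs_interruption_rate <- if (qs_min > 0) sum(flanked) / qs_min else NA_real_

  pair_names <- c("A-Q", "A-P", "Q-A", "Q-P", "P-A", "P-Q")
  transitions <- stats::setNames(integer(6), pair_names)
  if (nrow(staged$bouts) > 1) {
    from <- substr(staged$bouts$stage[-nrow(staged$bouts)], 1, 1)
    to <- substr(staged$bouts$stage[-1], 1, 1)
    key <- paste(from, to, sep = "-")
    tb <- table(key[from != to])
    transitions[names(tb)[names(tb) %in% pair_names]] <-
      as.integer(tb[names(tb) %in% pair_names])
  }

  qs_rows <- labeled[lab == "QS", ]
  qs_band_pct <- if (nrow(qs_rows) > 0) {
    100 * c(delta = mean(qs_rows$delta_fr), theta = mean(qs_rows$theta_fr),
            alpha = mean(qs_rows$alpha_fr), beta = mean(qs_rows$beta_fr))
  } else {
    c(delta = NA_real_, theta = NA_real_, alpha = NA_real_, beta = NA_real_)
  }

  structure(
    list(time_pct = time_pct, mean_bout_s = mean_bout_s,
         interruption_rate = interruption_rate,
         qs_interruption_rate = qs_interruption_rate,
         transitions = transitions, qs_band_pct = qs_band_pct,
         n_valid_epochs = n_valid, valid_min = valid_min),
    class = "somnark_architecture"
  )
}

#' @export
print.somnark_architecture <- function(x, ...) {
  cat("<somnark_architecture> over", round(x$valid_min, 1), "valid min\n")
  cat("  time %:", paste(STAGES, round(x$time_pct, 1), collapse = ", "), "\n")
  cat("  interruptions:", round(x$interruption_rate, 3), "/min (all),",
      round(x$qs_interruption_rate, 3), "/QS-min\n")
  invisible(x)
}

#' Tidy a sleep-architecture result into a long tibble
#'
#' @param x A `somnark_architecture`.
#' @param ... Unused.
#' @return A tibble with `metric` and `value` columns, mirroring the rows of
#'   a sleep-structure report (AW/QS/PS %, interruption rates, transition
#'   counts, QS band percentages).
#' @method tidy somnark_architecture
#' @export
tidy.somnark_architecture <- function(x, ...) {
  tibble::tibble(
    metric = c(paste0(STAGES, "_pct"), paste0(STAGES, "_bout_s"),
               "interruption_per_min", "qs_interruption_per_min",
               paste0("trans_", names(x$transitions)),
               paste0("qs_", names(x$qs_band_pct), "_pct")),
    value = unname(c(x$time_pct, x$mean_bout_s, x$interruption_rate,
                     x$qs_interruption_rate, x$transitions, x$qs_band_pct))
  )
}

#' Compare predicted stage labels with ground truth
#'
#' @param predicted Character/factor vector of predicted labels
#'   (AW/QS/PS/ERR) or a tibble with a `label` column.
#' @param truth Character vector of true labels, same length.
#' @return A list with `confusion` (truth x predicted table), `accuracy`
#'   (over epochs not predicted ERR) and `n_scored`.
#' @export
staging_recovery_report <- function(predicted, truth) {
  pred <- as.character(if (is.data.frame(predicted)) predicted$label
                       else predicted)
  if (length(pred) != length(truth)) {
    stop("predicted and truth label series differ in length", call. = FALSE)
  }
  keep <- pred != "ERR"
  conf <- table(truth = factor(truth, STAGES),
                predicted = factor(pred, c(STAGES, "ERR")))
  list(
    confusion = conf,
    accuracy = mean(pred[keep] == truth[keep]),
    n_scored = sum(keep)
  )
}

#' Write hypnogram and bout tables to CSV
#'
#' @param labeled Tibble from [classify_epochs()].
#' @param staged List from [form_stages()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_hypnogram_csv <- function(labeled, staged, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "hypnogram.csv")
  write.csv(labeled[, c("epoch_index", "t_start_s", "label")], p1,
            row.names = FALSE)
  p2 <- file.path(dir, "bouts.csv")
  write.csv(staged$bouts[, c("stage", "start_s", "end_s", "n_epochs")], p2,
            row.names = FALSE)
  invisible(c(p1, p2))
}
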
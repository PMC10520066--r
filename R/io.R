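# --- Minimal EDF (European Data Format) support -----------------------------
# EDF is the interchange standard for polysomnography. Only the plain EDF
# profile is implemented: ASCII header, one-second data records, 16-bit
# little-endian samples. This is a deliberately small reader/writer for the
# package's three-channel recordings, not a general EDF library.

pad <- function(x, width) {
  formatC(substr(as.character(x), 1, width), width = -width)
}

#' Write a recording to an EDF file
#'
#' Writes EEG/EMG/ECG channels with their true sampling rates, one data
#' record per second. EDF stores 16-bit integers, so sample values are
#' quantized to the per-channel physical range.
#'
#' @param rec A `somnark_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  chans <- list(
    list(label = "EEG", x = rec$eeg, fs = rec$fs[["eeg"]],
         prefilter = "HP:0.16Hz LP:48Hz"),
    list(label = "EMG", x = rec$emg, fs = rec$fs[["emg"]],
         prefilter = "HP:34Hz LP:103Hz"),
    list(label = "ECG", x = rec$ecg, fs = rec$fs[["ecg"]],
         prefilter = "HP:0.72Hz LP:103Hz")
  )
  n_rec <- floor(min(vapply(chans, function(c) length(c$x) / c$fs,
                            numeric(1))))
  ns <- length(chans)
  con <- file(path, "wb")
  on.exit(close(con))

  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad(1, 8),
    pad(ns, 4)
  ), con, eos = NULL)

  # physical limits must fit EDF's 8-char ASCII fields; quantization below
  # uses exactly the values a reader will parse back from those fields
  fmt8 <- function(v) {
    s <- formatC(v, format = "g", digits = 5)
    if (nchar(s) > 8) s <- formatC(v, format = "e", digits = 1)
    s
  }
  lim_str <- lapply(chans, function(c) {
    r <- range(c$x)
    if (diff(r) == 0) r <- r + c(-1, 1)
    # widen marginally so the true min/max stay inside the parsed limits
    r <- r + c(-1, 1) * 1e-3 * diff(r)
    s <- c(fmt8(r[1]), fmt8(r[2]))
    stopifnot(nchar(s) <= 8, as.numeric(s[1]) <= min(c$x),
              as.numeric(s[2]) >= max(c$x))
    s
  })
  lims <- lapply(lim_str, as.numeric)
  field <- function(f) paste(vapply(seq_len(ns), f, character(1)),
                             collapse = "")
  writeChar(paste0(
    field(function(i) pad(chans[[i]]$label, 16)),
    field(function(i) pad("", 80)),
    field(function(i) pad("uV", 8)),
    field(function(i) pad(lim_str[[i]][1], 8)),
    field(function(i) pad(lim_str[[i]][2], 8)),
    field(function(i) pad(-32768, 8)),
    field(function(i) pad(32767, 8)),
    field(function(i) pad(chans[[i]]$prefilter, 80)),
    field(function(i) pad(chans[[i]]$fs, 8)),
    field(function(i) pad("", 32))
  ), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      fs <- chans[[i]]$fs
      seg <- chans[[i]]$x[((r - 1) * fs + 1):(r * fs)]
      pmin_ <- lims[[i]][1]
      pmax_ <- lims[[i]][2]
      dig <- round((seg - pmin_) / (pmax_ - pmin_) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A list with `labels`, `fs` (samples per second per channel) and
#'   `signals` (list of numeric vectors in physical units).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  fld <- function(off, w) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig, off + (i - 1) * w + 1, off + i * w))
    }, character(1))
  }
  labels <- fld(0, 16)
  pmin_ <- as.numeric(fld(ns * (16 + 80 + 8), 8))
  pmax_ <- as.numeric(fld(ns * (16 + 80 + 8 + 8), 8))
  dmin <- as.numeric(fld(ns * (16 + 80 + 8 + 8 + 8), 8))
  dmax <- as.numeric(fld(ns * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(fld(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))

  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  signals <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  offs <- c(0, cumsum(spr))
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    base <- (r - 1) * per_rec
    for (i in seq_len(ns)) {
      d <- raw[(base + offs[i] + 1):(base + offs[i + 1])]
      signals[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin_[i] + (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i])
    }
  }
  list(labels = labels, fs = spr / rec_dur, signals = signals)
}

# --- Recording containers ---------------------------------------------------

#' Read a recording from disk
#'
#' `format = "edf"` reads an EDF file and maps channels to the EEG/EMG/ECG
#' roles by label pattern (case-insensitive regex), validating the expected
#' sampling rates (125/250/500 Hz). `format = "internal"` reads the
#' package's lossless serialized container. `"auto"` decides by file
#' extension.
#'
#' @param path File path.
#' @param format `"auto"`, `"edf"` or `"internal"`.
#' @param label_patterns Named character regexes locating each channel role.
#' @return A `somnark_recording` (without ground truth unless the internal
#'   container carried one).
#' @export
read_recording <- function(path, format = c("auto", "edf", "internal"),
                           label_patterns = c(eeg = "EEG", emg = "EMG",
                                              ecg = "ECG")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "internal"
  }
  if (format == "internal") {
    rec <- readRDS(path)
    if (!inherits(rec, "somnark_recording")) {
      stop("not a somnark recording container", call. = FALSE)
    }
    return(rec)
  }
  edf <- read_edf(path)
  expected_fs <- c(eeg = FS_EEG, emg = FS_EMG, ecg = FS_ECG)
  chan <- list()
  for (role in names(label_patterns)) {
    hit <- grep(label_patterns[[role]], edf$labels, ignore.case = TRUE)
    if (length(hit) == 0) {
      stop("EDF file is missing a channel matching role '", role, "'",
           call. = FALSE)
    }
    hit <- hit[1]
    if (abs(edf$fs[hit] - expected_fs[[role]]) > 1e-6) {
      stop("channel '", edf$labels[hit], "' has rate ", edf$fs[hit],
           " Hz; role '", role, "' requires ", expected_fs[[role]], " Hz",
           call. = FALSE)
    }
    chan[[role]] <- edf$signals[[hit]]
  }
  rec <- list(
    eeg = chan$eeg, emg = chan$emg, ecg = chan$ecg,
    fs = expected_fs, epoch_len_s = 8,
    duration_s = length(chan$eeg) / FS_EEG,
    truth = NULL, config = NULL,
    provenance = list(source = path)
  )
  class(rec) <- "somnark_recording"
  rec
}

#' Write a recording to disk
#'
#' @param rec A `somnark_recording`.
#' @param path Output path.
#' @param format `"edf"` (16-bit quantized interchange) or `"internal"`
#'   (lossless).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "internal")) {
  format <- match.arg(format)
  if (format == "edf") write_edf(rec, path) else saveRDS(rec, path)
  invisible(path)
}

#' Write ground-truth sidecar files
#'
#' Writes the synthetic recording's true hypnogram
#' (`<stem>_truth_labels.csv`: epoch_index, label) and beat times
#' (`<stem>_truth_beats.csv`: beat_time_s) next to an exported recording.
#'
#' @param rec A synthetic `somnark_recording`.
#' @param stem Path stem for the sidecar files.
#' @return Paths of the written files, invisibly.
#' @export
write_ground_truth <- function(rec, stem) {
  if (is.null(rec$truth)) stop("recording carries no ground truth",
                               call. = FALSE)
  p1 <- paste0(stem, "_truth_labels.csv")
  write.csv(data.frame(epoch_index = seq_along(rec$truth$labels),
                       label = rec$truth$labels), p1, row.names = FALSE)
  p2 <- paste0(stem, "_truth_beats.csv")
  write.csv(data.frame(beat_time_s = rec$truth$beat_times), p2,
            row.names = FALSE)
  invisible(c(p1, p2))
}
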
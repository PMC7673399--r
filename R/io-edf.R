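#' @include eeg-pipeline.R
NULL

# Minimal continuous EDF support (16-bit, one recording per file).

padField <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = -width, flag = " ")
}

#' Write an EEG record to an EDF file
#'
#' Continuous EDF with 16-bit samples and one-second data records;
#' per-channel physical ranges are taken from the data, so the round-trip
#' error is bounded by `(max - min) / 65535` per channel. Samples beyond a
#' whole number of records are truncated.
#'
#' @param record an [EEGRecord-class]; its sampling rate must be an
#'   integer.
#' @param path output path.
#' @param recordDuration data-record duration in seconds (default 1).
#' @return the path, invisibly.
#' @export
writeEDF <- function(record, path, recordDuration = 1) {
  fs <- record@samplingRate
  spr <- fs * recordDuration
  if (abs(spr - round(spr)) > 1e-9)
    stop("samples per data record must be an integer")
  spr <- as.integer(round(spr))
  ns <- nrow(record@data)
  nRec <- ncol(record@data) %/% spr
  if (nRec < 1L) stop("record shorter than one EDF data record")
  physMin <- apply(record@data, 1L, min)
  physMax <- apply(record@data, 1L, max)
  flat <- physMax - physMin < 1e-12
  physMax[flat] <- physMin[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8L),
    padField(record@subjectId, 80L),
    padField(paste("condition:", record@condition), 80L),
    padField("01.01.20", 8L), padField("00.00.00", 8L),
    padField(256L + ns * 256L, 8L),
    padField("", 44L),
    padField(nRec, 8L),
    padField(format(recordDuration), 8L),
    padField(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(padField(record@channelLabels, 16L), collapse = ""),
    paste(rep(padField("", 80L), ns), collapse = ""),
    paste(rep(padField("uV", 8L), ns), collapse = ""),
    paste(padField(formatC(physMin, format = "g", digits = 6), 8L),
          collapse = ""),
    paste(padField(formatC(physMax, format = "g", digits = 6), 8L),
          collapse = ""),
    paste(rep(padField("-32768", 8L), ns), collapse = ""),
    paste(rep(padField("32767", 8L), ns), collapse = ""),
    paste(rep(padField("", 80L), ns), collapse = ""),
    paste(rep(padField(spr, 8L), ns), collapse = ""),
    paste(rep(padField("", 32L), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)
  # headers echo physical limits at 6 significant digits; use the echoed
  # values for scaling so read-back inverts exactly
  pmin <- as.numeric(formatC(physMin, format = "g", digits = 6))
  pmax <- as.numeric(formatC(physMax, format = "g", digits = 6))
  scale <- 65535 / (pmax - pmin)
  for (r in seq_len(nRec)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    block <- matrix(0L, spr, ns)
    for (ch in seq_len(ns)) {
      dig <- round((record@data[ch, idx] - pmin[ch]) * scale[ch]) - 32768
      block[, ch] <- as.integer(pmin(pmax(dig, -32768), 32767))
    }
    writeBin(as.integer(as.vector(block)), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEGRecord
#'
#' Reads continuous 16-bit EDF as written by [writeEDF()] (and by common
#' acquisition software): all data records are concatenated.
#'
#' @param path EDF file path.
#' @param condition condition tag to attach (`"eyes_open"` or
#'   `"eyes_closed"`); read from the recording-id field if tagged there.
#' @return an [EEGRecord-class].
#' @export
readEDF <- function(path, condition = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8L)                              # version
  subj <- rd(80L)
  recId <- rd(80L)
  rd(8L); rd(8L); rd(8L); rd(44L)
  nRec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  invisible(replicate(ns, rd(80L)))                 # transducer
  invisible(replicate(ns, rd(8L)))                  # dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  invisible(replicate(ns, rd(80L)))                 # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), integer(1))
  invisible(replicate(ns, rd(32L)))
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  data <- matrix(0, ns, nRec * spr[1L])
  for (r in seq_len(nRec)) {
    raw <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, spr[1L], ns)
    for (ch in seq_len(ns)) {
      phys <- physMin[ch] + (block[, ch] - digMin[ch]) *
        (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
      data[ch, (r - 1L) * spr[1L] + seq_len(spr[1L])] <- phys
    }
  }
  if (is.null(condition)) {
    condition <- if (grepl("eyes_closed", recId)) "eyes_closed"
                 else "eyes_open"
  }
  eegRecord(subj, data, samplingRate = spr[1L] / dur,
            condition = condition, channelLabels = labels)
}

#' Save / load an epoch store
#'
#' Serializes an [EEGEpochSet-class] (single-plane data plus subject ids,
#' labels and channel metadata) to an RDS container; depth replication is
#' re-applied at model-input time, bit-identically.
#'
#' @param epochs an [EEGEpochSet-class].
#' @param path file path (`.rds`).
#' @return `readEpochStore` returns the [EEGEpochSet-class].
#' @export
writeEpochStore <- function(epochs, path) {
  saveRDS(list(data = epochs@data, subject_id = epochs@subjectId,
               label = epochs@label, window = epochs@window,
               channel_labels = epochs@channelLabels),
          path)
  invisible(path)
}

#' @rdname writeEpochStore
#' @export
readEpochStore <- function(path) {
  s <- readRDS(path)
  methods::new("EEGEpochSet", data = s$data, subjectId = s$subject_id,
               label = s$label, window = s$window,
               channelLabels = s$channel_labels)
}
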
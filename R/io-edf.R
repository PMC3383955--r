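#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Minimal EDF (European Data Format) support for continuous recordings.
# One data record per second; 16-bit little-endian samples; physical units
# microvolts. Event markers travel in a TSV sidecar (see readEventsTSV).
# ---------------------------------------------------------------------------

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.edfNum <- function(x, width) .edfPad(format(x, trim = TRUE, digits = 8,
                                             scientific = FALSE), width)

#' Write a ContinuousRecording to an EDF file
#'
#' Plain EDF, one data record per second, 16-bit samples. Each channel is
#' scaled to its own symmetric physical range, so the quantization step is
#' \code{2 * max(abs(x)) / 65535} microvolts. The recording length must be a
#' whole number of seconds (the generator's trial period guarantees this).
#' Events are not stored in the EDF; use [writeEventsTSV()].
#'
#' @param recording a [ContinuousRecording-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeRecordingEDF <- function(recording, path) {
  stopifnot(is(recording, "ContinuousRecording"))
  fs <- recording@fsHz
  if (abs(fs - round(fs)) > 1e-9)
    stop("writeRecordingEDF: sampling rate must be an integer number of Hz")
  fs <- as.integer(round(fs))
  dat <- recording@data
  ns <- ncol(dat)
  if (ns %% fs != 0L)
    stop("writeRecordingEDF: recording length must be a whole number of seconds")
  nRec <- ns %/% fs
  nSig <- nrow(dat)
  labels <- recording@channelLabels

  physMax <- pmax(apply(abs(dat), 1, max), 1)
  physMax <- signif(physMax * 1.0001, 8)   # strictly contain the data
  digMax <- 32767; digMin <- -32768
  scale <- (2 * physMax) / (digMax - digMin)
  digital <- matrix(0L, nSig, ns)
  for (i in seq_len(nSig))
    digital[i, ] <- as.integer(round((dat[i, ] + physMax[i]) / scale[i]) +
                                 digMin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8),
    .edfPad("X X X X", 80),
    .edfPad("Startdate 01-JAN-2000 X X X", 80),
    "01.01.00", "00.00.00",
    .edfNum(256L * (nSig + 1L), 8),
    .edfPad("", 44),
    .edfNum(nRec, 8),
    .edfNum(1L, 8),
    .edfNum(nSig, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(labels, .edfPad, "", width = 16),
    vapply(rep("AgAgCl electrode", nSig), .edfPad, "", width = 80),
    vapply(rep("uV", nSig), .edfPad, "", width = 8),
    vapply(-physMax, .edfNum, "", width = 8),
    vapply(physMax, .edfNum, "", width = 8),
    vapply(rep(digMin, nSig), .edfNum, "", width = 8),
    vapply(rep(digMax, nSig), .edfNum, "", width = 8),
    vapply(rep("", nSig), .edfPad, "", width = 80),
    vapply(rep(fs, nSig), .edfNum, "", width = 8),
    vapply(rep("", nSig), .edfPad, "", width = 32))
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(digital[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

.edfReadField <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Read a ContinuousRecording from an EDF file
#'
#' Reads a continuous EDF written by [writeRecordingEDF()] (or any plain EDF
#' with identical record length for all signals). Data are returned in the
#' file's physical units (microvolts for generator output); the sampling
#' rate is taken from the header. Channel labels outside the montage the
#' generator uses trigger a labelled warning but are passed through.
#'
#' @param path EDF file path.
#' @param eventsPath optional TSV of event markers ([readEventsTSV()]);
#'   events beyond the end of the recording are a hard error.
#' @param knownLabels channel labels considered part of the montage.
#' @return A [ContinuousRecording-class].
#' @export
readRecordingEDF <- function(path, eventsPath = NULL,
                             knownLabels = .defaultMontage()) {
  if (!file.exists(path)) stop("readRecordingEDF: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                       # version
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)         # ids, date, time
  headerBytes <- as.integer(.edfReadField(con, 8))
  readChar(con, 44, useBytes = TRUE)
  nRec <- as.integer(.edfReadField(con, 8))
  recDur <- as.numeric(.edfReadField(con, 8))
  nSig <- as.integer(.edfReadField(con, 4))
  rd <- function(width) vapply(seq_len(nSig), function(i)
    .edfReadField(con, width), "")
  labels <- rd(16)
  rd(80)                                                  # transducer
  rd(8)                                                   # dimension
  physMin <- as.numeric(rd(8))
  physMax <- as.numeric(rd(8))
  digMin <- as.numeric(rd(8))
  digMax <- as.numeric(rd(8))
  rd(80)                                                  # prefiltering
  spr <- as.integer(rd(8))                                # samples per record
  rd(32)
  seek(con, headerBytes)
  if (length(unique(spr)) != 1L)
    stop("readRecordingEDF: signals with differing record lengths are not supported")
  fs <- spr[1] / recDur
  unknown <- setdiff(labels, knownLabels)
  if (length(unknown))
    warning("readRecordingEDF: unknown channel label(s): ",
            paste(unknown, collapse = ", "), " (passed through)")
  n <- nRec * spr[1]
  raw <- readBin(con, what = "integer", n = nSig * n, size = 2L,
                 signed = TRUE, endian = "little")
  dat <- matrix(0, nSig, n, dimnames = list(labels, NULL))
  for (r in seq_len(nRec)) {
    offset <- (r - 1L) * nSig * spr[1]
    for (i in seq_len(nSig)) {
      seg <- raw[(offset + (i - 1L) * spr[1] + 1L):(offset + i * spr[1])]
      dat[i, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        physMin[i] + (seg - digMin[i]) *
          (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    }
  }
  events <- data.frame(sample_index = integer(), label = character())
  if (!is.null(eventsPath)) {
    events <- readEventsTSV(eventsPath)
    if (any(events$sample_index >= n))
      stop("readRecordingEDF: event beyond recording end")
  }
  new("ContinuousRecording", fsHz = fs, channelLabels = labels, data = dat,
      events = events)
}
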
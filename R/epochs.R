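#' @include AllClasses.R
NULL

.parseCueLabel <- function(label) {
  nogo <- label == "nogo"
  parts <- strsplit(label, "_", fixed = TRUE)
  width <- vapply(parts, function(p) if (length(p) == 4L)
    as.numeric(p[2]) else NA_real_, 0)
  id <- vapply(parts, function(p) if (length(p) == 4L)
    as.numeric(p[3]) else NA_real_, 0)
  hand <- vapply(parts, function(p) if (length(p) == 4L) p[4] else
    NA_character_, "")
  data.frame(label = label, width = width, id = id,
             amplitude = ifelse(nogo, NA_real_, width * 2^id / 2),
             hand = hand, isNogo = nogo, stringsAsFactors = FALSE)
}

#' Cut a continuous recording into time-locked epochs
#'
#' Extracts one epoch per locking event. Epoch windows are half-open
#' \code{[start, end)} in ms relative to the locking event; a sample at time
#' \code{t} is included when \code{start <= t < end}. Cue-locked epochs
#' (\code{lock = "cue"}) are triggered by directional-cue and no-go markers
#' and labelled from the cue; go- and lift-locked epochs inherit the
#' condition of the preceding cue. Events too close to a recording edge are
#' dropped with a logged reason.
#'
#' @param recording a [ContinuousRecording-class].
#' @param lock \code{"cue"}, \code{"go"} or \code{"lift"}.
#' @param windowMs half-open window in ms relative to the lock event
#'   (default \code{c(-300, 1500)} for cue locking, the response-locked
#'   default being \code{c(-800, 200)} around the stylus lift).
#' @param trials optional behavioural table ([simulateBehaviour()] /
#'   [readBehaviourTSV()]); rows are matched to epochs via the cue onset
#'   sample and contribute \code{subject}, \code{miss}, \code{wrongTarget},
#'   \code{rt} and \code{mt} columns.
#' @param conditionMap optional named character vector mapping cue labels to
#'   analysis conditions; a cue label without an entry is an error.
#' @return An [EpochSet-class] (not yet baseline-corrected).
#' @export
epochRecording <- function(recording, lock = c("cue", "go", "lift"),
                           windowMs = NULL, trials = NULL,
                           conditionMap = NULL) {
  stopifnot(is(recording, "ContinuousRecording"))
  lock <- match.arg(lock)
  if (is.null(windowMs))
    windowMs <- if (lock == "lift") c(-800, 200) else c(-300, 1500)
  fs <- recording@fsHz
  ev <- recording@events
  isCue <- grepl("^cue_", ev$label) | ev$label == "nogo"
  lockIdx <- switch(lock,
    cue = which(isCue),
    go = which(ev$label == "go"),
    lift = which(ev$label == "lift"))
  if (!length(lockIdx)) stop("epochRecording: no '", lock, "' events found")

  # condition of each lock event = its own cue, or the preceding cue marker
  cueRows <- which(isCue)
  owner <- vapply(lockIdx, function(i) {
    prev <- cueRows[cueRows <= i]
    if (!length(prev)) NA_integer_ else prev[length(prev)]
  }, 0L)
  if (any(is.na(owner)))
    stop("epochRecording: lock event without a preceding cue marker")
  cond <- .parseCueLabel(ev$label[owner])
  cond$cueSample <- ev$sample_index[owner]

  if (!is.null(conditionMap)) {
    unmapped <- setdiff(unique(cond$label), names(conditionMap))
    if (length(unmapped))
      stop("epochRecording: unmapped condition(s): ",
           paste(unmapped, collapse = ", "))
    cond$condition <- unname(conditionMap[cond$label])
  }
  if (!is.null(trials)) {
    cueSmp <- as.integer(round(trials$cueOnsetMs * fs / 1000))
    m <- match(cond$cueSample, cueSmp)
    if (any(is.na(m)))
      stop("epochRecording: epochs without a matching behavioural trial")
    for (col in intersect(c("subject", "block", "miss", "wrongTarget",
                            "rt", "mt"), names(trials)))
      cond[[col]] <- trials[[col]][m]
  }

  startOff <- as.integer(round(windowMs[1] * fs / 1000))
  nT <- as.integer(round((windowMs[2] - windowMs[1]) * fs / 1000))
  lockSmp <- ev$sample_index[lockIdx]
  first <- lockSmp + startOff
  ok <- first >= 0L & (first + nT) <= ncol(recording@data)
  if (any(!ok))
    message("epochRecording: dropped ", sum(!ok),
            " epoch(s) too close to a recording edge")
  first <- first[ok]
  cond <- cond[ok, , drop = FALSE]
  rownames(cond) <- NULL

  nEp <- length(first)
  nCh <- nrow(recording@data)
  dat <- array(0, c(nEp, nCh, nT))
  for (e in seq_len(nEp))
    dat[e, , ] <- recording@data[, (first[e] + 1L):(first[e] + nT)]
  new("EpochSet", data = dat, fsHz = fs,
      channelLabels = recording@channelLabels,
      timesMs = windowMs[1] + (0:(nT - 1L)) * 1000 / fs,
      lockEvent = lock, windowMs = as.numeric(windowMs),
      baselineMs = numeric(), conditions = cond,
      rejected = rep(FALSE, nEp), rejectReason = rep("", nEp))
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (half-open, in ms relative to the lock event). Re-applying the same
#' correction leaves the data unchanged.
#'
#' @param epochs an [EpochSet-class].
#' @param baselineMs numeric length 2; default \code{c(-200, 0)}, the last
#'   200 ms before the locking event.
#' @return The corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, baselineMs = c(-200, 0)) {
  stopifnot(is(epochs, "EpochSet"))
  if (baselineMs[1] < epochs@windowMs[1] || baselineMs[2] > epochs@windowMs[2])
    stop("baselineCorrect: baseline window must lie within the epoch window")
  sel <- epochs@timesMs >= baselineMs[1] & epochs@timesMs < baselineMs[2]
  if (!any(sel)) stop("baselineCorrect: baseline window contains no samples")
  d <- epochs@data
  bl <- apply(d[, , sel, drop = FALSE], c(1, 2), mean)
  epochs@data <- d - as.vector(bl)   # bl recycles over the 3rd dimension
  epochs@baselineMs <- as.numeric(baselineMs)
  epochs
}

#' Flag epochs containing peak-to-peak artifacts
#'
#' An epoch is rejected when the difference between its maximum and minimum
#' value within the segment exceeds the threshold (strictly) on any of the
#' inspected channels; the flag records the offending channel. By default
#' only EEG channels are inspected, because the bipolar HEOG channel carries
#' task-driven saccade deflections larger than the threshold; pass EOG
#' channel names explicitly to include them. Flags accumulate: an epoch
#' rejected earlier stays rejected, so lowering the threshold never
#' un-rejects an epoch.
#'
#' @param epochs an [EpochSet-class].
#' @param thresholdUv peak-to-peak threshold in microvolts (default 100).
#' @param channels channels to inspect (default all EEG channels).
#' @return The [EpochSet-class] with updated rejection flags.
#' @export
rejectArtifacts <- function(epochs, thresholdUv = 100, channels = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  if (thresholdUv <= 0) stop("rejectArtifacts: threshold must be positive")
  if (is.null(channels)) channels <- .eegChannelsOf(epochs@channelLabels)
  chIdx <- match(channels, epochs@channelLabels)
  if (any(is.na(chIdx)))
    stop("rejectArtifacts: unknown channel(s): ",
         paste(channels[is.na(chIdx)], collapse = ", "))
  d <- epochs@data
  for (e in seq_len(dim(d)[1])) {
    seg <- d[e, chIdx, , drop = FALSE]
    p2p <- apply(seg, 2, function(x) max(x) - min(x))
    bad <- which(p2p > thresholdUv)
    if (length(bad) && !epochs@rejected[e]) {
      epochs@rejected[e] <- TRUE
      epochs@rejectReason[e] <- sprintf("p2p %.1f uV on %s",
                                        p2p[bad[1]], channels[bad[1]])
    }
  }
  epochs
}

#' Average accepted epochs into per-condition ERPs
#'
#' Arithmetic mean over accepted (non-rejected) epochs, grouped by the given
#' condition columns. A requested condition with no accepted epoch is an
#' error naming the condition.
#'
#' @param epochs an [EpochSet-class].
#' @param by character, condition columns to group by (default
#'   \code{"label"}).
#' @param excludeRejected exclude flagged epochs (default \code{TRUE};
#'   rejected epochs are never part of an average unless this is disabled
#'   explicitly for diagnostics).
#' @return An [ErpSet-class] with one average per condition and an \code{n}
#'   column counting the averaged epochs.
#' @export
averageEpochs <- function(epochs, by = "label", excludeRejected = TRUE) {
  stopifnot(is(epochs, "EpochSet"))
  cond <- epochs@conditions
  missing <- setdiff(by, names(cond))
  if (length(missing))
    stop("averageEpochs: unknown condition column(s): ",
         paste(missing, collapse = ", "))
  key <- do.call(paste, c(cond[by], sep = "|"))
  groups <- unique(key)
  keep <- if (excludeRejected) !epochs@rejected else rep(TRUE, length(key))
  d <- epochs@data
  out <- array(0, c(length(groups), dim(d)[2], dim(d)[3]))
  n <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- which(key == groups[g] & keep)
    if (!length(idx))
      stop("averageEpochs: no accepted epochs for condition ", groups[g])
    n[g] <- length(idx)
    out[g, , ] <- colMeans(d[idx, , , drop = FALSE])
  }
  condOut <- cond[match(groups, key), by, drop = FALSE]
  condOut$n <- n
  rownames(condOut) <- NULL
  new("ErpSet", data = out, conditions = condOut, fsHz = epochs@fsHz,
      channelLabels = epochs@channelLabels, timesMs = epochs@timesMs,
      lockEvent = epochs@lockEvent)
}
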
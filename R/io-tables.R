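#' @include AllClasses.R
NULL

.eventLabelPattern <- "^(cue_[0-9.]+_[0-9.]+_(left|right)|nogo|go|lift|tap)$"

#' Write event markers to TSV
#'
#' Two columns, \code{sample_index} (0-based) and \code{label}; UTF-8, unix
#' newlines, "." decimal separator.
#'
#' @param events data.frame with \code{sample_index} and \code{label}, or a
#'   [ContinuousRecording-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeEventsTSV <- function(events, path) {
  if (is(events, "ContinuousRecording")) events <- eventTable(events)
  stopifnot(all(c("sample_index", "label") %in% names(events)))
  utils::write.table(events[, c("sample_index", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}

#' Read event markers from TSV
#'
#' Rows are sorted by \code{sample_index} on load (with a warning if the file
#' was unsorted); labels outside the declared vocabulary
#' (\code{cue_<width>_<id>_<hand>}, \code{nogo}, \code{go}, \code{lift},
#' \code{tap}) are an error, as is an empty table.
#'
#' @param path TSV file with columns \code{sample_index}, \code{label}.
#' @return data.frame sorted by \code{sample_index}.
#' @export
readEventsTSV <- function(path) {
  if (!file.exists(path)) stop("readEventsTSV: file not found: ", path)
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_index", "label") %in% names(ev)))
    stop("readEventsTSV: header must declare sample_index and label")
  if (nrow(ev) == 0L) stop("readEventsTSV: no events")
  bad <- !grepl(.eventLabelPattern, ev$label)
  if (any(bad))
    stop("readEventsTSV: label(s) outside the declared vocabulary: ",
         paste(unique(ev$label[bad]), collapse = ", "))
  if (any(ev$sample_index < 0))
    stop("readEventsTSV: negative sample_index")
  if (is.unsorted(ev$sample_index)) {
    warning("readEventsTSV: events were not sorted by sample_index; sorting")
    ev <- ev[order(ev$sample_index), ]
  }
  rownames(ev) <- NULL
  ev
}

.behaviourColumns <- c("subject", "block", "trialInBlock", "cueType",
                       "isNogo", "hand", "width", "amplitude", "id",
                       "idLevel", "rt", "mt", "miss", "wrongTarget",
                       "cueOnsetMs", "goOnsetMs", "liftMs", "tapMs")

#' Write a behavioural trial table to TSV
#'
#' One row per trial, columns as produced by [simulateBehaviour()]; no-go
#' trials have empty \code{rt}/\code{mt} fields.
#'
#' @param trials behavioural trial data.frame.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeBehaviourTSV <- function(trials, path) {
  stopifnot(all(.behaviourColumns %in% names(trials)))
  utils::write.table(trials[, .behaviourColumns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a behavioural trial table from TSV
#'
#' The stored index of difficulty is recomputed from amplitude and width and
#' checked against the stored column; a deviation beyond 1e-9 is an
#' integrity error. No-go rows (empty \code{rt}/\code{mt}) are accepted.
#'
#' @param path TSV file written by [writeBehaviourTSV()].
#' @return Typed data.frame of trials.
#' @export
readBehaviourTSV <- function(path) {
  if (!file.exists(path)) stop("readBehaviourTSV: file not found: ", path)
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(.behaviourColumns, names(tr))
  if (length(missing))
    stop("readBehaviourTSV: missing column(s): ",
         paste(missing, collapse = ", "))
  act <- !tr$isNogo
  idc <- computeID(tr$amplitude[act], tr$width[act])
  if (any(abs(idc - tr$id[act]) > 1e-9))
    stop("readBehaviourTSV: integrity error: stored ID differs from ",
         "log2(2*amplitude/width)")
  for (col in c("isNogo", "miss", "wrongTarget"))
    tr[[col]] <- as.logical(tr[[col]])
  tr
}
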
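#' @include epochs.R stats.R
NULL

.windowSel <- function(timesMs, windowMs) {
  sel <- timesMs >= windowMs[1] & timesMs < windowMs[2]
  if (!any(sel)) stop("window [", windowMs[1], ", ", windowMs[2],
                      ") ms contains no samples")
  sel
}

.chanIdx <- function(labels, channels, what) {
  idx <- match(channels, labels)
  if (any(is.na(idx)))
    stop(what, ": missing electrode(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  idx
}

#' Default parieto-occipital region of interest for the posterior N2/P3b
#'
#' @return Character vector of the six ROI electrode labels.
#' @export
posteriorRoi <- function() c("Pz", "P1", "P2", "POz", "PO3", "PO4")

#' Region-of-interest window mean of condition ERPs
#'
#' Pools the ERP over the ROI electrodes (mean over electrodes, then mean
#' over the half-open time window). The default ROI and window quantify the
#' posterior N2/P3b complex: electrodes Pz, P1, P2, POz, PO3, PO4, 310-370
#' ms after cue onset (the window is exposed because a 310-350 ms variant is
#' sometimes used for display).
#'
#' @param erps an [ErpSet-class].
#' @param channels ROI electrode labels (default [posteriorRoi()]).
#' @param windowMs half-open window in ms relative to the lock event
#'   (default \code{c(310, 370)}).
#' @param measureName value stored in the output's \code{measure} column.
#' @return The [conditionTable()] of \code{erps} with a \code{value} column
#'   (microvolts) and a \code{measure} column.
#' @export
roiWindowMean <- function(erps, channels = posteriorRoi(),
                          windowMs = c(310, 370), measureName = "n2p3b") {
  stopifnot(is(erps, "ErpSet"))
  chIdx <- .chanIdx(erps@channelLabels, channels, "roiWindowMean")
  sel <- .windowSel(erps@timesMs, windowMs)
  out <- erps@conditions
  # mean over electrodes then over time: both are plain arithmetic means,
  # so a single mean over the electrode x time block is identical
  out$value <- vapply(seq_len(dim(erps@data)[1]), function(i)
    mean(erps@data[i, chIdx, sel]), 0)
  out$measure <- measureName
  out
}

#' Motor CNV: action-minus-no-go fronto-central window mean
#'
#' Subtracts the no-go condition's ERP from each action-planning condition's
#' ERP (removing stimulus-anticipation activity, keeping the motor part of
#' the contingent negative variation), pools electrodes Cz, FCz, CPz, C1 and
#' C2 with equal weights, and averages over the last 200 ms before go
#' onset — for cue-locked epochs with a 1000 ms foreperiod, 800-1000 ms
#' after cue onset.
#'
#' @param erps cue-locked [ErpSet-class] whose conditions include the no-go
#'   average.
#' @param electrodes pooled electrodes.
#' @param windowMs half-open window in ms after cue onset (default
#'   \code{c(800, 1000)} = the last 200 ms of the foreperiod).
#' @param nogoLabel condition label of the no-go average.
#' @param labelColumn condition column holding the labels (default
#'   \code{"label"}).
#' @return Condition table of the action conditions with a \code{value}
#'   column (microvolts) and \code{measure = "motor_cnv"}.
#' @export
motorCNV <- function(erps, electrodes = c("Cz", "FCz", "CPz", "C1", "C2"),
                     windowMs = c(800, 1000), nogoLabel = "nogo",
                     labelColumn = "label") {
  stopifnot(is(erps, "ErpSet"))
  chIdx <- .chanIdx(erps@channelLabels, electrodes, "motorCNV")
  sel <- .windowSel(erps@timesMs, windowMs)
  labels <- erps@conditions[[labelColumn]]
  nogoRow <- which(labels == nogoLabel)
  if (length(nogoRow) != 1L)
    stop("motorCNV: no-go condition '", nogoLabel, "' absent")
  nogoMean <- mean(erps@data[nogoRow, chIdx, sel])
  action <- setdiff(seq_along(labels), nogoRow)
  out <- erps@conditions[action, , drop = FALSE]
  out$value <- vapply(action, function(i)
    mean(erps@data[i, chIdx, sel]) - nogoMean, 0)
  out$measure <- "motor_cnv"
  rownames(out) <- NULL
  out
}

#' Lateralized readiness potential by double subtraction
#'
#' For each electrode pair (left, right), computes
#' \code{0.5 * ((left - right)[right hand] + (right - left)[left hand])},
#' pools the pairs with equal weights, and averages over the last 200 ms
#' before response onset (the stylus-lift marker used for response locking).
#' Hand-specific motor-cortex activation contralateral to the responding
#' hand appears as a negative value; activity identical for both hands
#' cancels exactly, and swapping the hand labels flips the sign exactly.
#'
#' @param leftErp,rightErp response-locked [ErpSet-class] objects (or
#'   channels x samples matrices) for left- and right-hand responses. When
#'   ErpSets with several conditions are given, rows are matched on all
#'   shared condition columns except \code{hand} and \code{n}.
#' @param pairs list of c(left electrode, right electrode) pairs (default
#'   C1/C2 and C3/C4).
#' @param windowMs half-open window in ms relative to response onset
#'   (default \code{c(-200, 0)}).
#' @param timesMs time axis, required when matrices are supplied.
#' @return data.frame with the matched condition columns (if any), a
#'   \code{value} column (microvolts) and \code{measure = "lrp"}.
#' @export
lrpAmplitude <- function(leftErp, rightErp,
                         pairs = list(c("C1", "C2"), c("C3", "C4")),
                         windowMs = c(-200, 0), timesMs = NULL) {
  if (is.matrix(leftErp) != is.matrix(rightErp))
    stop("lrpAmplitude: both hands must be given in the same form")
  if (is.matrix(leftErp)) {
    if (is.null(timesMs)) stop("lrpAmplitude: timesMs required for matrices")
    labels <- rownames(leftErp)
    sel <- .windowSel(timesMs, windowMs)
    val <- .lrpValue(leftErp[, sel, drop = FALSE],
                     rightErp[, sel, drop = FALSE], labels, pairs)
    return(data.frame(value = val, measure = "lrp"))
  }
  stopifnot(is(leftErp, "ErpSet"), is(rightErp, "ErpSet"))
  sel <- .windowSel(leftErp@timesMs, windowMs)
  keyCols <- setdiff(intersect(names(leftErp@conditions),
                               names(rightErp@conditions)),
                     c("hand", "n", "label", "cueSample"))
  lKey <- do.call(paste, c(leftErp@conditions[keyCols], sep = "|"))
  rKey <- do.call(paste, c(rightErp@conditions[keyCols], sep = "|"))
  m <- match(lKey, rKey)
  if (any(is.na(m)))
    stop("lrpAmplitude: missing right-hand average for condition(s): ",
         paste(lKey[is.na(m)], collapse = ", "))
  out <- leftErp@conditions[, keyCols, drop = FALSE]
  out$value <- vapply(seq_along(m), function(i) {
    L <- leftErp@data[i, , sel, drop = FALSE]
    R <- rightErp@data[m[i], , sel, drop = FALSE]
    dim(L) <- dim(L)[2:3]; dim(R) <- dim(R)[2:3]
    .lrpValue(L, R, leftErp@channelLabels, pairs)
  }, 0)
  out$measure <- "lrp"
  out
}

.lrpValue <- function(leftHandDat, rightHandDat, labels, pairs) {
  vals <- vapply(pairs, function(pr) {
    iL <- .chanIdx(labels, pr[1], "lrpAmplitude")
    iR <- .chanIdx(labels, pr[2], "lrpAmplitude")
    0.5 * ((mean(rightHandDat[iL, ]) - mean(rightHandDat[iR, ])) +
             (mean(leftHandDat[iR, ]) - mean(leftHandDat[iL, ])))
  }, 0)
  mean(vals)
}

#' Lateralized horizontal EOG amplitude
#'
#' Quantifies horizontal eye-movement amplitude from the bipolar HEOG
#' channel: trials are sign-aligned so that the gaze-toward-target
#' deflection is negative (left-target trials are flipped), averaged across
#' sides within each condition, and the mean over 250-450 ms after go-signal
#' onset is taken. Works on cue-locked epochs (the window is shifted by the
#' foreperiod) or go-locked epochs.
#'
#' @param epochs an [EpochSet-class] with an \code{HEOG} channel and a
#'   \code{hand} condition column giving the target side; rejected, miss and
#'   wrong-target epochs are excluded.
#' @param by condition columns defining the reported cells (default
#'   \code{c("width", "id")}).
#' @param windowMs half-open window in ms after go onset (default
#'   \code{c(250, 450)}).
#' @param goOnsetMs go onset relative to the lock event; defaults to 1000
#'   (the foreperiod) for cue-locked epochs and 0 otherwise.
#' @param channel HEOG channel name.
#' @return data.frame with the \code{by} columns, \code{n}, \code{value}
#'   (microvolts) and \code{measure = "lheog"}.
#' @export
lateralizedHEOG <- function(epochs, by = c("width", "id"),
                            windowMs = c(250, 450), goOnsetMs = NULL,
                            channel = "HEOG") {
  stopifnot(is(epochs, "EpochSet"))
  chIdx <- .chanIdx(epochs@channelLabels, channel, "lateralizedHEOG")
  if (is.null(goOnsetMs))
    goOnsetMs <- if (epochs@lockEvent == "cue") 1000 else 0
  sel <- .windowSel(epochs@timesMs, windowMs + goOnsetMs)
  cond <- epochs@conditions
  keep <- !epochs@rejected & !cond$isNogo
  for (fl in intersect(c("miss", "wrongTarget"), names(cond)))
    keep <- keep & !cond[[fl]]
  if (!any(keep)) stop("lateralizedHEOG: no usable epochs")
  sides <- unique(cond$hand[keep])
  if (length(sides) < 2L)
    warning("lateralizedHEOG: only ", sides,
            "-target trials present; computed from one side")
  sign <- ifelse(cond$hand == "left", -1, 1)
  key <- do.call(paste, c(cond[by], sep = "|"))
  groups <- unique(key[keep])
  rows <- lapply(groups, function(g) {
    idx <- which(key == g & keep)
    out <- cond[idx[1], by, drop = FALSE]
    out$n <- length(idx)
    out$value <- mean(vapply(idx, function(e)
      sign[e] * mean(epochs@data[e, chIdx, sel]), 0))
    out
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[by]), , drop = FALSE]
  out$measure <- "lheog"
  rownames(out) <- NULL
  out
}

#' Regress condition-level ERP measures on ID or amplitude
#'
#' Ordinary least squares of per-condition measure values (e.g. the grand
#' average over subjects) on the index of difficulty or the movement
#' amplitude; same contract as [fittsRegression()].
#'
#' @param measures data.frame with a \code{value} column and the predictor
#'   column.
#' @param predictor \code{"id"} or \code{"amplitude"}.
#' @return A [RegressionResult-class].
#' @export
erpRegression <- function(measures, predictor = c("id", "amplitude")) {
  predictor <- match.arg(predictor)
  if (!predictor %in% names(measures)) {
    if (predictor == "amplitude" && all(c("width", "id") %in% names(measures)))
      measures$amplitude <- measures$width * 2^measures$id / 2
    else stop("erpRegression: predictor column not found: ", predictor)
  }
  if (length(unique(measures[[predictor]])) < 3L)
    stop("erpRegression: need >= 3 distinct predictor values")
  olsFit(measures[[predictor]], measures$value, predictor)
}
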
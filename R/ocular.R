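#' @include AllClasses.R
NULL

.eogChannelsOf <- function(labels) intersect(c("VEOG", "HEOG"), labels)
.eegChannelsOf <- function(labels) setdiff(labels, c("VEOG", "HEOG"))

# epochs x channels x time -> per-channel residuals after subtracting the
# condition-wise event-related average from every single trial
.conditionResiduals <- function(dat, condition) {
  res <- dat
  for (g in unique(condition)) {
    idx <- which(condition == g)
    avg <- colMeans(dat[idx, , , drop = FALSE])
    for (i in idx) res[i, , ] <- dat[i, , ] - avg
  }
  res
}

#' Fit a regression-based ocular-correction model
#'
#' Estimates EOG-to-EEG propagation coefficients in the Gratton-Coles
#' manner: the condition-wise event-related average is subtracted from every
#' single trial (so that stimulus-locked brain activity does not masquerade
#' as ocular propagation), and each EEG channel's coefficient is the pooled
#' \code{cov(EOG residual, EEG residual) / var(EOG residual)} over all
#' trials and samples. Vertical and horizontal EOG are fitted sequentially:
#' vertical first, horizontal on the vertical-corrected residuals. A single
#' combined coefficient per EOG channel is used (no separate blink/saccade
#' classes).
#'
#' Note that regressing out the horizontal EOG is a double-edged sword when
#' lateralized motor measures are of interest: residual-based coefficient
#' estimates pick up response-locked brain activity that covaries with the
#' task saccade, and the resulting over- or under-correction leaks the
#' (large) saccade potential into hemispheric difference waves such as the
#' LRP. The default pipeline therefore corrects vertical EOG only; pass
#' \code{eogChannels = c("VEOG", "HEOG")} to fit both.
#'
#' @param epochs an [EpochSet-class] containing the EOG channels and at
#'   least 2 epochs per condition; fitting normally precedes filtering and
#'   rejection.
#' @param conditionColumn name of the condition column used for the
#'   event-related average subtraction (default \code{"label"}).
#' @param eogChannels which EOG channels to fit (default: all present, in
#'   vertical-then-horizontal order).
#' @return An [OcularModel-class].
#' @export
fitOcularModel <- function(epochs, conditionColumn = "label",
                           eogChannels = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  labels <- epochs@channelLabels
  eog <- .eogChannelsOf(labels)
  if (!is.null(eogChannels)) {
    bad <- setdiff(eogChannels, eog)
    if (length(bad))
      stop("fitOcularModel: not an available EOG channel: ",
           paste(bad, collapse = ", "))
    eog <- intersect(eog, eogChannels)
  }
  eeg <- .eegChannelsOf(labels)
  if (length(eog) == 0L) stop("fitOcularModel: no EOG channels present")
  if (dim(epochs@data)[3] < 2L)
    stop("fitOcularModel: epochs too short (variance undefined)")
  cond <- epochs@conditions[[conditionColumn]]
  if (is.null(cond)) stop("fitOcularModel: condition column not found: ",
                          conditionColumn)
  if (any(table(cond) < 2L))
    stop("fitOcularModel: need >= 2 epochs per condition")
  res <- .conditionResiduals(epochs@data, cond)
  coefs <- matrix(0, length(eog), length(eeg),
                  dimnames = list(eog, eeg))
  eegRes <- lapply(eeg, function(ch) as.vector(res[, match(ch, labels), ]))
  names(eegRes) <- eeg
  for (e in eog) {
    v <- as.vector(res[, match(e, labels), ])
    vv <- stats::var(v)
    if (!is.finite(vv) || vv <= .Machine$double.eps)
      stop("fitOcularModel: flat EOG (zero variance on ", e, ")")
    for (ch in eeg) {
      coefs[e, ch] <- stats::cov(v, eegRes[[ch]]) / vv
      # sequential fit: later EOG channels see corrected residuals
      eegRes[[ch]] <- eegRes[[ch]] - coefs[e, ch] * v
    }
  }
  new("OcularModel", eogChannels = eog, eegChannels = eeg,
      coefficients = coefs)
}

.applyOcularToMatrix <- function(dat, labels, model) {
  missing <- setdiff(c(model@eogChannels, model@eegChannels), labels)
  if (length(missing))
    stop("applyOcularModel: channel(s) not present in data: ",
         paste(missing, collapse = ", "))
  for (e in model@eogChannels) {
    eogTrace <- dat[match(e, labels), ]
    for (ch in model@eegChannels)
      dat[match(ch, labels), ] <- dat[match(ch, labels), ] -
        model@coefficients[e, ch] * eogTrace
  }
  dat
}

#' @rdname applyOcularModel
#' @export
setMethod("applyOcularModel", "ContinuousRecording", function(x, model) {
  x@data <- .applyOcularToMatrix(x@data, x@channelLabels, model)
  x
})

#' @rdname applyOcularModel
#' @export
setMethod("applyOcularModel", "EpochSet", function(x, model) {
  d <- x@data
  for (e in seq_len(dim(d)[1])) {
    m <- d[e, , , drop = FALSE]
    dim(m) <- dim(d)[2:3]
    d[e, , ] <- .applyOcularToMatrix(m, x@channelLabels, model)
  }
  x@data <- d
  x
})
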
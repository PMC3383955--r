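#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# ExperimentDesign
# ---------------------------------------------------------------------------

#' ExperimentDesign: the factorial trial plan of the pre-cued tapping task
#'
#' Holds the full design of the experiment: target widths, per-cell movement
#' amplitudes and indices of difficulty (ID), the hands, the cue vocabulary
#' (directional cues plus a no-go cue), block structure and trial timing.
#' Within a block the target width is constant; each of the cue types occurs
#' equally often. Amplitudes satisfy \code{ID = log2(2 * amplitude / width)}
#' exactly.
#'
#' @slot widths numeric, target widths in cm.
#' @slot ids numeric, the ID levels (bits).
#' @slot cells data.frame with one row per width x ID cell: \code{width},
#'   \code{id}, \code{amplitude} (centre-to-centre distance, cm) and
#'   \code{idLevel} (rank of the ID within the block; the far target has the
#'   highest rank).
#' @slot hands character, \code{c("left", "right")}.
#' @slot cueTypes character, the cue vocabulary used within a block:
#'   one directional cue per ID level and hand, plus \code{"nogo"}.
#' @slot nBlocks integer, number of experimental blocks.
#' @slot trialsPerBlock integer.
#' @slot blockDurationS numeric, block duration in seconds
#'   (= trialsPerBlock * trialPeriodMs / 1000).
#' @slot timing named list: \code{fixationMs}, \code{cueMs},
#'   \code{foreperiodMs} (cue onset to go onset), \code{goMs},
#'   \code{trialPeriodMs}.
#' @seealso [buildDesign()]
#' @export
setClass("ExperimentDesign",
  representation(
    widths = "numeric", ids = "numeric", cells = "data.frame",
    hands = "character", cueTypes = "character",
    nBlocks = "integer", trialsPerBlock = "integer",
    blockDurationS = "numeric", timing = "list"
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  cells <- object@cells
  if (!all(c("width", "id", "amplitude", "idLevel") %in% names(cells)))
    msg <- c(msg, "cells must have columns width, id, amplitude, idLevel")
  else {
    idc <- log2(2 * cells$amplitude / cells$width)
    if (any(abs(idc - cells$id) > 1e-12))
      msg <- c(msg, "cell IDs do not satisfy id == log2(2*amplitude/width)")
  }
  need <- c("fixationMs", "cueMs", "foreperiodMs", "goMs", "trialPeriodMs")
  if (!all(need %in% names(object@timing)))
    msg <- c(msg, paste("timing must contain", paste(need, collapse = ", ")))
  else if (abs(object@trialsPerBlock * object@timing$trialPeriodMs -
               object@blockDurationS * 1000) > 1e-9)
    msg <- c(msg, "trialsPerBlock * trialPeriodMs must equal blockDurationS")
  if (object@trialsPerBlock %% length(object@cueTypes) != 0L)
    msg <- c(msg, "trialsPerBlock must be a multiple of the number of cue types")
  if (object@nBlocks %% length(object@widths) != 0L)
    msg <- c(msg, "nBlocks must be a multiple of the number of widths")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExperimentDesign", function(object) {
  cat("ExperimentDesign:", length(object@widths), "widths x",
      length(object@ids), "IDs,", object@nBlocks, "blocks of",
      object@trialsPerBlock, "trials (", object@blockDurationS, "s )\n")
  cat("  widths (cm):", paste(object@widths, collapse = ", "), "\n")
  cat("  IDs (bits): ", paste(object@ids, collapse = ", "), "\n")
  cat("  cue types:  ", paste(object@cueTypes, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# GeneratorConfig
# ---------------------------------------------------------------------------

#' GeneratorConfig: parameters of the synthetic experiment
#'
#' All parameters of the synthetic-data generator: the behavioural laws
#' (Fitts coefficients for movement time, ID-independent reaction times with
#' a hand advantage), the ERP component laws (posterior N2/P3b linear in ID,
#' lateralized HEOG linear in movement amplitude, ID-independent CNV and
#' LRP), artifact and noise parameters, per-cell error rates, montage and
#' sampling rate, and the master RNG seed.
#'
#' @slot nSubjects integer.
#' @slot fsHz numeric, sampling rate (Hz).
#' @slot seed integer, master RNG seed.
#' @slot mtInterceptMs,mtSlopeMsPerId numeric, movement-time law
#'   \code{MT = a + b * ID}.
#' @slot mtNoiseSdMs numeric, within-subject trial-to-trial MT SD.
#' @slot mtSubjectSdMs numeric, between-subject MT intercept SD.
#' @slot rtMeanMs,rtSdMs numeric, reaction-time mean/SD (independent of ID).
#' @slot rtSubjectSdMs numeric, between-subject RT intercept SD.
#' @slot rtHandOffsetMs numeric, mean right-hand RT advantage (ms; right
#'   hand faster by this amount).
#' @slot rtHandOffsetSdMs numeric, between-subject SD of the hand advantage.
#' @slot erpInterceptUv,erpSlopeUvPerId numeric, posterior N2/P3b window-mean
#'   law as a function of ID.
#' @slot erpSubjectSdUv numeric, between-subject SD of the N2/P3b intercept.
#' @slot heogInterceptUv,heogSlopeUvPerCm numeric, lateralized HEOG
#'   window-mean law as a function of movement amplitude.
#' @slot heogSubjectSdUv numeric.
#' @slot cnvAmpUv numeric, magnitude of the (negative) motor CNV ramp at go
#'   onset, action trials only; ID-independent by construction.
#' @slot cnvAnticipUv numeric, magnitude of the anticipatory CNV common to
#'   action and no-go trials (removed by the no-go subtraction).
#' @slot cnvSubjectSdUv numeric.
#' @slot lrpAmpUv numeric, magnitude of the (negative) lateralized motor
#'   potential contralateral to the responding hand; ID-independent.
#' @slot lrpSubjectSdUv numeric.
#' @slot blinkRateHz numeric, Poisson rate of blink artifacts.
#' @slot blinkAmpUv numeric, mean blink amplitude on VEOG.
#' @slot whiteSdUv,pinkSdUv numeric, white and 1/f noise SD per channel.
#' @slot pinkExponent numeric, spectral exponent of the 1/f noise.
#' @slot propagation list with named numeric vectors \code{veog} and
#'   \code{heog}: EOG-to-EEG propagation coefficient per EEG channel.
#' @slot errorRates numeric matrix (width x ID-level) of miss probabilities.
#' @slot wrongTargetRates numeric vector (per ID level / arrow size) of
#'   wrong-target probabilities.
#' @slot channelLabels character, montage (EEG labels plus VEOG, HEOG).
#' @seealso [generatorConfig()], [noiselessConfig()]
#' @export
setClass("GeneratorConfig",
  representation(
    nSubjects = "integer", fsHz = "numeric", seed = "integer",
    mtInterceptMs = "numeric", mtSlopeMsPerId = "numeric",
    mtNoiseSdMs = "numeric", mtSubjectSdMs = "numeric",
    rtMeanMs = "numeric", rtSdMs = "numeric", rtSubjectSdMs = "numeric",
    rtHandOffsetMs = "numeric", rtHandOffsetSdMs = "numeric",
    erpInterceptUv = "numeric", erpSlopeUvPerId = "numeric",
    erpSubjectSdUv = "numeric",
    heogInterceptUv = "numeric", heogSlopeUvPerCm = "numeric",
    heogSubjectSdUv = "numeric",
    cnvAmpUv = "numeric", cnvAnticipUv = "numeric", cnvSubjectSdUv = "numeric",
    lrpAmpUv = "numeric", lrpSubjectSdUv = "numeric",
    blinkRateHz = "numeric", blinkAmpUv = "numeric",
    whiteSdUv = "numeric", pinkSdUv = "numeric", pinkExponent = "numeric",
    propagation = "list",
    errorRates = "matrix", wrongTargetRates = "numeric",
    channelLabels = "character"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  sds <- c(object@mtNoiseSdMs, object@mtSubjectSdMs, object@rtSdMs,
           object@rtSubjectSdMs, object@rtHandOffsetSdMs, object@erpSubjectSdUv,
           object@heogSubjectSdUv, object@cnvSubjectSdUv, object@lrpSubjectSdUv,
           object@whiteSdUv, object@pinkSdUv, object@blinkRateHz)
  if (any(sds < 0)) msg <- c(msg, "all SDs and rates must be non-negative")
  if (object@fsHz <= 0) msg <- c(msg, "fsHz must be positive")
  if (any(object@errorRates < 0 | object@errorRates > 1) ||
      any(object@wrongTargetRates < 0 | object@wrongTargetRates > 1))
    msg <- c(msg, "error rates must lie in [0, 1]")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  eeg <- setdiff(object@channelLabels, c("VEOG", "HEOG"))
  for (e in c("veog", "heog")) {
    p <- object@propagation[[e]]
    if (is.null(p) || !all(eeg %in% names(p)))
      msg <- c(msg, sprintf("propagation$%s must name every EEG channel", e))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nSubjects, "subjects @", object@fsHz,
      "Hz, seed", object@seed, "\n")
  cat(sprintf("  MT (ms)      = %g + %g ID  (trial SD %g)\n",
              object@mtInterceptMs, object@mtSlopeMsPerId, object@mtNoiseSdMs))
  cat(sprintf("  N2/P3b (uV)  = %g + %g ID\n",
              object@erpInterceptUv, object@erpSlopeUvPerId))
  cat(sprintf("  LHEOG (uV)   = %g + %g amplitude\n",
              object@heogInterceptUv, object@heogSlopeUvPerCm))
  cat(sprintf("  CNV %g uV, LRP %g uV (both ID-independent)\n",
              object@cnvAmpUv, object@lrpAmpUv))
})

# ---------------------------------------------------------------------------
# ContinuousRecording
# ---------------------------------------------------------------------------

#' ContinuousRecording: multichannel EEG/EOG time series with event markers
#'
#' @slot fsHz numeric, sampling rate in Hz.
#' @slot channelLabels character, unique channel names (10-20 EEG labels and
#'   bipolar \code{VEOG}/\code{HEOG}).
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot events data.frame with 0-based \code{sample_index} (strictly
#'   increasing, within the recording) and \code{label}.
#' @seealso [simulateRecording()], [readRecordingEDF()]
#' @export
setClass("ContinuousRecording",
  representation(fsHz = "numeric", channelLabels = "character",
                 data = "matrix", events = "data.frame")
)

setValidity("ContinuousRecording", function(object) {
  msg <- character()
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "data row count must equal the number of channel labels")
  ev <- object@events
  if (nrow(ev)) {
    if (!all(c("sample_index", "label") %in% names(ev)))
      msg <- c(msg, "events must have columns sample_index, label")
    else {
      if (is.unsorted(ev$sample_index, strictly = TRUE))
        msg <- c(msg, "events must be strictly ordered by sample_index")
      if (any(ev$sample_index < 0) ||
          any(ev$sample_index >= ncol(object@data)))
        msg <- c(msg, "events must lie within the recording")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContinuousRecording", function(object) {
  cat("ContinuousRecording:", nrow(object@data), "channels x",
      ncol(object@data), "samples @", object@fsHz, "Hz (",
      round(ncol(object@data) / object@fsHz, 1), "s ),",
      nrow(object@events), "events\n")
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
})

#' @rdname fsHz
setMethod("fsHz", "ContinuousRecording", function(x) x@fsHz)
#' @rdname channelLabels
setMethod("channelLabels", "ContinuousRecording", function(x) x@channelLabels)
#' @rdname signalData
setMethod("signalData", "ContinuousRecording", function(x) x@data)
#' @rdname eventTable
setMethod("eventTable", "ContinuousRecording", function(x) x@events)

# ---------------------------------------------------------------------------
# EpochSet
# ---------------------------------------------------------------------------

#' EpochSet: condition-labelled, time-locked EEG segments
#'
#' Epoch windows are half-open \code{[start, end)} in ms relative to the
#' locking event; sample indices are 0-based. Rejected epochs stay in the
#' container but are excluded from every average.
#'
#' @slot data numeric array, epochs x channels x samples (microvolts).
#' @slot fsHz numeric.
#' @slot channelLabels character.
#' @slot timesMs numeric, per-sample time in ms relative to the lock event.
#' @slot lockEvent character, e.g. \code{"cue"}, \code{"go"} or
#'   \code{"lift"}.
#' @slot windowMs numeric length-2, the half-open epoch window.
#' @slot baselineMs numeric length 2 if baseline-corrected, length 0 if not.
#' @slot conditions data.frame, one row per epoch (condition labels, hand,
#'   width, id, amplitude, trial flags, subject).
#' @slot rejected logical per epoch.
#' @slot rejectReason character per epoch (\code{""} when kept).
#' @seealso [epochRecording()], [baselineCorrect()], [rejectArtifacts()]
#' @export
setClass("EpochSet",
  representation(
    data = "array", fsHz = "numeric", channelLabels = "character",
    timesMs = "numeric", lockEvent = "character", windowMs = "numeric",
    baselineMs = "numeric", conditions = "data.frame",
    rejected = "logical", rejectReason = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3D array")
  else {
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "dim 2 of data must match channelLabels")
    if (d[3] != length(object@timesMs))
      msg <- c(msg, "dim 3 of data must match timesMs")
    if (d[1] != nrow(object@conditions) || d[1] != length(object@rejected) ||
        d[1] != length(object@rejectReason))
      msg <- c(msg, "conditions/rejected/rejectReason must have one entry per epoch")
  }
  if (length(object@baselineMs) == 2L) {
    if (object@baselineMs[1] < object@windowMs[1] ||
        object@baselineMs[2] > object@windowMs[2])
      msg <- c(msg, "baseline window must lie within the epoch window")
  } else if (length(object@baselineMs) != 0L)
    msg <- c(msg, "baselineMs must have length 0 or 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", dim(object@data)[1], "epochs x",
      dim(object@data)[2], "channels x", dim(object@data)[3], "samples,",
      "locked to", object@lockEvent,
      sprintf("[%g, %g) ms", object@windowMs[1], object@windowMs[2]), "\n")
  cat("  rejected:", sum(object@rejected), "  baseline:",
      if (length(object@baselineMs)) sprintf("[%g, %g) ms",
        object@baselineMs[1], object@baselineMs[2]) else "none", "\n")
})

#' @rdname fsHz
setMethod("fsHz", "EpochSet", function(x) x@fsHz)
#' @rdname channelLabels
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @rdname signalData
setMethod("signalData", "EpochSet", function(x) x@data)
#' @rdname conditionTable
setMethod("conditionTable", "EpochSet", function(x) x@conditions)
#' @rdname timesMs
setMethod("timesMs", "EpochSet", function(x) x@timesMs)
#' @rdname rejected
setMethod("rejected", "EpochSet", function(x) x@rejected)
#' @rdname rejectReason
setMethod("rejectReason", "EpochSet", function(x) x@rejectReason)

#' Subset an EpochSet by epoch index
#'
#' @param x an [EpochSet-class].
#' @param i epoch indices (numeric or logical).
#' @param j,...,drop ignored.
#' @return An [EpochSet-class] with the selected epochs.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) return(x)
  if (is.logical(i)) i <- which(i)
  initialize(x,
    data = x@data[i, , , drop = FALSE],
    conditions = x@conditions[i, , drop = FALSE],
    rejected = x@rejected[i],
    rejectReason = x@rejectReason[i])
})

# ---------------------------------------------------------------------------
# ErpSet
# ---------------------------------------------------------------------------

#' ErpSet: per-condition event-related potentials
#'
#' The arithmetic mean over accepted epochs, one channels x samples plane per
#' condition.
#'
#' @slot data numeric array, conditions x channels x samples.
#' @slot conditions data.frame, one row per condition, including \code{n}
#'   (number of averaged epochs).
#' @slot fsHz numeric.
#' @slot channelLabels character.
#' @slot timesMs numeric.
#' @slot lockEvent character.
#' @seealso [averageEpochs()]
#' @export
setClass("ErpSet",
  representation(data = "array", conditions = "data.frame", fsHz = "numeric",
                 channelLabels = "character", timesMs = "numeric",
                 lockEvent = "character")
)

setValidity("ErpSet", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "data must be a 3D array")
  else {
    if (d[1] != nrow(object@conditions))
      msg <- c(msg, "one condition row per average required")
    if (d[2] != length(object@channelLabels) || d[3] != length(object@timesMs))
      msg <- c(msg, "data dimensions must match channelLabels and timesMs")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ErpSet", function(object) {
  cat("ErpSet:", dim(object@data)[1], "condition averages,",
      dim(object@data)[2], "channels, locked to", object@lockEvent, "\n")
})

#' Subset an ErpSet by condition row
#'
#' @param x an [ErpSet-class].
#' @param i condition indices (numeric or logical).
#' @param j,...,drop ignored.
#' @return An [ErpSet-class] with the selected condition averages.
#' @export
setMethod("[", "ErpSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) return(x)
  if (is.logical(i)) i <- which(i)
  initialize(x, data = x@data[i, , , drop = FALSE],
             conditions = x@conditions[i, , drop = FALSE])
})

#' @rdname fsHz
setMethod("fsHz", "ErpSet", function(x) x@fsHz)
#' @rdname channelLabels
setMethod("channelLabels", "ErpSet", function(x) x@channelLabels)
#' @rdname signalData
setMethod("signalData", "ErpSet", function(x) x@data)
#' @rdname conditionTable
setMethod("conditionTable", "ErpSet", function(x) x@conditions)
#' @rdname timesMs
setMethod("timesMs", "ErpSet", function(x) x@timesMs)

# ---------------------------------------------------------------------------
# OcularModel
# ---------------------------------------------------------------------------

#' OcularModel: regression-based EOG propagation coefficients
#'
#' One dimensionless propagation coefficient per (EOG channel, EEG channel)
#' pair, estimated on event-related-average-subtracted single-trial
#' residuals (vertical EOG first, horizontal EOG on vertical-corrected
#' residuals).
#'
#' @slot eogChannels character, the EOG channels in fitting order.
#' @slot eegChannels character.
#' @slot coefficients numeric matrix, EOG x EEG.
#' @seealso [fitOcularModel()], [applyOcularModel()]
#' @export
setClass("OcularModel",
  representation(eogChannels = "character", eegChannels = "character",
                 coefficients = "matrix")
)

setValidity("OcularModel", function(object) {
  msg <- character()
  if (nrow(object@coefficients) != length(object@eogChannels) ||
      ncol(object@coefficients) != length(object@eegChannels))
    msg <- c(msg, "coefficients must be eogChannels x eegChannels")
  if (any(!is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OcularModel", function(object) {
  cat("OcularModel:", paste(object@eogChannels, collapse = ", "), "->",
      length(object@eegChannels), "EEG channels\n")
  print(round(object@coefficients, 4))
})

# ---------------------------------------------------------------------------
# RegressionResult
# ---------------------------------------------------------------------------

#' RegressionResult: a simple ordinary-least-squares fit
#'
#' @slot slope,intercept numeric, the fitted line.
#' @slot r2 numeric in \code{[0, 1]}.
#' @slot fStat numeric, \code{F = (r2 / (1 - r2)) * dfDen}.
#' @slot dfNum,dfDen numeric degrees of freedom (1 and n - 2).
#' @slot p numeric, upper-tail F probability.
#' @slot n integer, number of points fitted.
#' @slot predictor character, name of the predictor.
#' @slot slopeSe numeric, standard error of the slope.
#' @seealso [olsFit()]
#' @export
setClass("RegressionResult",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 fStat = "numeric", dfNum = "numeric", dfDen = "numeric",
                 p = "numeric", n = "integer", predictor = "character",
                 slopeSe = "numeric")
)

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("y = %.4g + %.4g %s;  r2 = %.3f, F(%g, %g) = %.4g, p = %.3g (n = %d)\n",
              object@intercept, object@slope,
              if (length(object@predictor)) object@predictor else "x",
              object@r2, object@dfNum, object@dfDen, object@fStat, object@p,
              object@n))
})

#' Coefficients of a RegressionResult
#'
#' @param object a [RegressionResult-class].
#' @param ... ignored.
#' @return Named numeric vector \code{c(intercept, slope)}.
#' @export
setMethod("coef", "RegressionResult", function(object, ...)
  c(intercept = object@intercept, slope = object@slope))
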
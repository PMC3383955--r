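#' @include AllGenerics.R
NULL

#' Sampling rate accessor
#'
#' @param x an object with a sampling rate (a [ContinuousRecording-class],
#'   [EpochSet-class] or [ErpSet-class]).
#' @return Sampling rate in Hz.
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))

#' Channel label accessor
#'
#' @param x an object holding multichannel data.
#' @return Character vector of channel labels (10-20 names plus bipolar
#'   \code{VEOG}/\code{HEOG}).
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Signal data accessor
#'
#' @param x a [ContinuousRecording-class] (channels x samples matrix),
#'   [EpochSet-class] (epochs x channels x samples array) or
#'   [ErpSet-class] (conditions x channels x samples array).
#' @return The numeric data container, in microvolts.
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' Event marker accessor
#'
#' @param x a [ContinuousRecording-class].
#' @return A data.frame with columns \code{sample_index} (0-based) and
#'   \code{label}.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' Per-epoch / per-condition metadata accessor
#'
#' @param x an [EpochSet-class] or [ErpSet-class].
#' @return A data.frame with one row per epoch (or averaged condition).
#' @export
setGeneric("conditionTable", function(x) standardGeneric("conditionTable"))

#' Epoch time axis accessor
#'
#' @param x an [EpochSet-class] or [ErpSet-class].
#' @return Numeric vector of sample times in ms relative to the locking event.
#' @export
setGeneric("timesMs", function(x) standardGeneric("timesMs"))

#' Rejection flag accessor
#'
#' @param x an [EpochSet-class].
#' @return Logical vector, one element per epoch.
#' @export
setGeneric("rejected", function(x) standardGeneric("rejected"))

#' Rejection reason accessor
#'
#' @param x an [EpochSet-class].
#' @return Character vector, one element per epoch (\code{""} if kept).
#' @export
setGeneric("rejectReason", function(x) standardGeneric("rejectReason"))

#' Band-pass filter multichannel EEG
#'
#' Zero-phase Butterworth band-pass. The filter is applied in the frequency
#' domain using the squared Butterworth magnitude response, which is the
#' exact transfer function of a forward-backward (filtfilt) pass and is
#' numerically stable even for sub-0.1 Hz high-pass cutoffs, where
#' time-domain IIR recursions accumulate rounding error. The effective
#' roll-off therefore exceeds the nominal 24 dB/octave of a single pass.
#'
#' @param x a [ContinuousRecording-class] or [EpochSet-class].
#' @param hpHz high-pass cutoff in Hz (default 0.05).
#' @param lpHz low-pass cutoff in Hz (default 60).
#' @param order filter order per section (default 4, i.e. 24 dB/octave).
#' @return The same container with filtered EEG/EOG data.
#' @export
setGeneric("bandpass", function(x, hpHz = 0.05, lpHz = 60, order = 4L)
  standardGeneric("bandpass"))

#' Apply a fitted ocular-correction model
#'
#' Subtracts the propagated EOG contribution from every EEG channel:
#' \code{corrected = EEG - sum_e beta_e * EOG_e}. EOG channels themselves are
#' left unchanged.
#'
#' @param x a [ContinuousRecording-class] or [EpochSet-class].
#' @param model an [OcularModel-class] from [fitOcularModel()].
#' @return The corrected container.
#' @export
setGeneric("applyOcularModel", function(x, model)
  standardGeneric("applyOcularModel"))
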
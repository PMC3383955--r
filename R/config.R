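#' @include AllClasses.R
NULL

.defaultMontage <- function() {
  c("Pz", "P1", "P2", "POz", "PO3", "PO4",
    "Cz", "FCz", "CPz", "C1", "C2", "C3", "C4",
    "VEOG", "HEOG")
}

# blink (VEOG) propagation: posterior-to-frontal gradient 0.05-0.30;
# HEOG propagation: small, lateralized, antisymmetric left/right on the
# parieto-occipital sites and zero at the centro-parietal sites (horizontal
# EOG falls off steeply with distance from the eyes, and any residual
# antisymmetric propagation at C1-C4 that regression-based correction fails
# to remove would masquerade as an amplitude-dependent LRP)
.defaultPropagation <- function() {
  list(
    veog = c(Pz = 0.10, P1 = 0.10, P2 = 0.10, POz = 0.06, PO3 = 0.05,
             PO4 = 0.05, Cz = 0.22, FCz = 0.30, CPz = 0.15, C1 = 0.20,
             C2 = 0.20, C3 = 0.18, C4 = 0.18),
    heog = c(Pz = 0, P1 = 0.01, P2 = -0.01, POz = 0, PO3 = 0.02,
             PO4 = -0.02, Cz = 0, FCz = 0, CPz = 0, C1 = 0,
             C2 = 0, C3 = 0, C4 = 0)
  )
}

# per-cell miss rates (%/100), rows = widths 1,2,4 cm, cols = near/mid/far
.defaultErrorRates <- function() {
  m <- rbind(`1` = c(0.007, 0.020, 0.018),
             `2` = c(0.003, 0.005, 0.008),
             `4` = c(0.001, 0.003, 0.003))
  colnames(m) <- c("near", "mid", "far")
  m
}

#' Create a synthetic-experiment configuration
#'
#' Returns a [GeneratorConfig-class] whose defaults encode the study
#' conditions the analysis is built for: 17 subjects, movement times
#' following \code{MT = 211 + 68 ID} ms (trial SD 40 ms), ID-independent
#' reaction times around 360 ms with a 15 ms right-hand advantage, a
#' posterior N2/P3b window mean following \code{-2.3 + 1.6 ID} microvolts, a
#' lateralized HEOG window mean following \code{-133 - 3.8 amplitude}
#' microvolts, ID-independent CNV and LRP components, blink artifacts
#' propagated to the scalp, 1/f plus white background noise, and per-cell
#' miss rates between 0.1% and 2%.
#'
#' @param nSubjects number of subjects (default 17).
#' @param fsHz sampling rate in Hz (default 500).
#' @param seed master RNG seed; identical seed and config give bit-identical
#'   output.
#' @param mtInterceptMs,mtSlopeMsPerId,mtNoiseSdMs,mtSubjectSdMs movement-time
#'   law and noise.
#' @param rtMeanMs,rtSdMs,rtSubjectSdMs,rtHandOffsetMs,rtHandOffsetSdMs
#'   reaction-time parameters.
#' @param erpInterceptUv,erpSlopeUvPerId,erpSubjectSdUv posterior N2/P3b law.
#' @param heogInterceptUv,heogSlopeUvPerCm,heogSubjectSdUv lateralized HEOG law.
#' @param cnvAmpUv,cnvAnticipUv,cnvSubjectSdUv CNV amplitudes.
#' @param lrpAmpUv,lrpSubjectSdUv LRP amplitude.
#' @param blinkRateHz,blinkAmpUv blink artifact parameters.
#' @param whiteSdUv,pinkSdUv,pinkExponent background-noise parameters.
#' @param propagation list of named vectors \code{veog}, \code{heog}.
#' @param errorRates width x ID-level miss-probability matrix.
#' @param wrongTargetRates per-ID-level wrong-target probabilities.
#' @param channelLabels montage.
#' @return A validated [GeneratorConfig-class].
#' @seealso [noiselessConfig()]
#' @export
generatorConfig <- function(nSubjects = 17L, fsHz = 500, seed = 1L,
                            mtInterceptMs = 211, mtSlopeMsPerId = 68,
                            mtNoiseSdMs = 40, mtSubjectSdMs = 25,
                            rtMeanMs = 360, rtSdMs = 70, rtSubjectSdMs = 40,
                            rtHandOffsetMs = 15, rtHandOffsetSdMs = 20,
                            erpInterceptUv = -2.3, erpSlopeUvPerId = 1.6,
                            erpSubjectSdUv = 0.4,
                            heogInterceptUv = -133, heogSlopeUvPerCm = -3.8,
                            heogSubjectSdUv = 5,
                            cnvAmpUv = 4, cnvAnticipUv = 2, cnvSubjectSdUv = 1,
                            lrpAmpUv = 2, lrpSubjectSdUv = 0.5,
                            blinkRateHz = 0.05, blinkAmpUv = 200,
                            whiteSdUv = 3, pinkSdUv = 4, pinkExponent = 1,
                            propagation = .defaultPropagation(),
                            errorRates = .defaultErrorRates(),
                            wrongTargetRates = c(near = 0.001, mid = 0.002,
                                                 far = 0.002),
                            channelLabels = .defaultMontage()) {
  new("GeneratorConfig",
      nSubjects = as.integer(nSubjects), fsHz = fsHz, seed = as.integer(seed),
      mtInterceptMs = mtInterceptMs, mtSlopeMsPerId = mtSlopeMsPerId,
      mtNoiseSdMs = mtNoiseSdMs, mtSubjectSdMs = mtSubjectSdMs,
      rtMeanMs = rtMeanMs, rtSdMs = rtSdMs, rtSubjectSdMs = rtSubjectSdMs,
      rtHandOffsetMs = rtHandOffsetMs, rtHandOffsetSdMs = rtHandOffsetSdMs,
      erpInterceptUv = erpInterceptUv, erpSlopeUvPerId = erpSlopeUvPerId,
      erpSubjectSdUv = erpSubjectSdUv,
      heogInterceptUv = heogInterceptUv, heogSlopeUvPerCm = heogSlopeUvPerCm,
      heogSubjectSdUv = heogSubjectSdUv,
      cnvAmpUv = cnvAmpUv, cnvAnticipUv = cnvAnticipUv,
      cnvSubjectSdUv = cnvSubjectSdUv,
      lrpAmpUv = lrpAmpUv, lrpSubjectSdUv = lrpSubjectSdUv,
      blinkRateHz = blinkRateHz, blinkAmpUv = blinkAmpUv,
      whiteSdUv = whiteSdUv, pinkSdUv = pinkSdUv, pinkExponent = pinkExponent,
      propagation = propagation, errorRates = errorRates,
      wrongTargetRates = wrongTargetRates, channelLabels = channelLabels)
}

#' Noise-free configuration for exact-recovery checks
#'
#' A [generatorConfig()] with every noise SD, artifact amplitude,
#' between-subject SD and error rate set to zero. Downstream measures then
#' recover the generating laws exactly.
#'
#' @param ... overrides passed on to [generatorConfig()].
#' @return A [GeneratorConfig-class].
#' @export
noiselessConfig <- function(...) {
  generatorConfig(mtNoiseSdMs = 0, mtSubjectSdMs = 0, rtSdMs = 0,
                  rtSubjectSdMs = 0, rtHandOffsetSdMs = 0,
                  erpSubjectSdUv = 0, heogSubjectSdUv = 0,
                  cnvSubjectSdUv = 0, lrpSubjectSdUv = 0,
                  blinkRateHz = 0, whiteSdUv = 0, pinkSdUv = 0,
                  errorRates = .defaultErrorRates() * 0,
                  wrongTargetRates = c(near = 0, mid = 0, far = 0),
                  ...)
}

# ---------------------------------------------------------------------------
# RNG stream derivation: one master seed, per-subject child streams.
# Stream order (documented contract): for subject s,
#   effects stream  seed = (master + 104729 * s)     mod 2^31-1
#   behaviour stream seed = effects seed + 1
#   recording stream seed = effects seed + 2
# ---------------------------------------------------------------------------
.subjectSeed <- function(config, subject, stream = c("effects", "behaviour",
                                                     "recording")) {
  stream <- match.arg(stream)
  base <- (as.double(config@seed) + 104729 * as.double(subject)) %% 2147483647
  as.integer(base) + c(effects = 0L, behaviour = 1L, recording = 2L)[[stream]]
}

# Per-subject random effects, drawn in a fixed, documented order from the
# subject's effects stream.
.subjectEffects <- function(config, subject) {
  set.seed(.subjectSeed(config, subject, "effects"))
  list(
    mtIntercept = stats::rnorm(1, 0, config@mtSubjectSdMs),
    rtIntercept = stats::rnorm(1, 0, config@rtSubjectSdMs),
    rtHandOffset = stats::rnorm(1, config@rtHandOffsetMs,
                                config@rtHandOffsetSdMs),
    erpIntercept = stats::rnorm(1, 0, config@erpSubjectSdUv),
    heogIntercept = stats::rnorm(1, 0, config@heogSubjectSdUv),
    cnvAmp = stats::rnorm(1, 0, config@cnvSubjectSdUv),
    lrpAmp = stats::rnorm(1, 0, config@lrpSubjectSdUv)
  )
}

# ---------------------------------------------------------------------------
# JSON round trip for configurations
# ---------------------------------------------------------------------------

.configSlotNames <- function() {
  setdiff(slotNames("GeneratorConfig"), character())
}

#' Write a GeneratorConfig to JSON
#'
#' @param config a [GeneratorConfig-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeConfigJSON <- function(config, path) {
  stopifnot(is(config, "GeneratorConfig"))
  x <- lapply(.configSlotNames(), function(s) slot(config, s))
  names(x) <- .configSlotNames()
  x$errorRates <- list(values = unname(x$errorRates),
                       widths = rownames(config@errorRates),
                       idLevels = colnames(config@errorRates))
  x$propagation <- lapply(x$propagation, as.list)
  x$wrongTargetRates <- as.list(x$wrongTargetRates)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a GeneratorConfig from JSON
#'
#' Unknown keys are rejected so that configuration typos fail loudly.
#'
#' @param path JSON file written by [writeConfigJSON()].
#' @return A validated [GeneratorConfig-class].
#' @export
readConfigJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), .configSlotNames())
  if (length(unknown))
    stop("readConfigJSON: unknown config keys: ", paste(unknown, collapse = ", "))
  er <- matrix(unlist(x$errorRates$values), nrow = length(x$errorRates$widths),
               dimnames = list(x$errorRates$widths, x$errorRates$idLevels))
  args <- x[setdiff(names(x), c("errorRates", "propagation",
                                "wrongTargetRates"))]
  args$errorRates <- er
  args$propagation <- lapply(x$propagation, unlist)
  args$wrongTargetRates <- unlist(x$wrongTargetRates)
  do.call(generatorConfig, args)
}
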
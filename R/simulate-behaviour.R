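#' @include config.R design.R
NULL

.parseCueType <- function(cueType, design, blockWidth) {
  nogo <- cueType == "nogo"
  k <- rep(NA_integer_, length(cueType))
  k[!nogo] <- as.integer(sub("^id([0-9]+)_.*$", "\\1", cueType[!nogo]))
  hand <- ifelse(nogo, NA_character_, sub("^id[0-9]+_", "", cueType))
  id <- design@ids[k]
  list(isNogo = nogo, idLevel = k, hand = hand, id = id,
       width = ifelse(nogo, NA_real_, blockWidth),
       amplitude = ifelse(nogo, NA_real_, blockWidth * 2^id / 2))
}

.cellMissRate <- function(config, design, widthRank, idLevel) {
  er <- config@errorRates
  if (nrow(er) < length(design@widths) || ncol(er) < length(design@ids))
    stop("errorRates matrix is smaller than the design grid")
  er[cbind(widthRank, idLevel)]
}

#' Simulate the behavioural outcome of the pre-cued tapping experiment
#'
#' Draws one row per trial for every requested subject. Movement times follow
#' \code{Normal(a + b * ID, mtNoiseSdMs)} plus a subject-level intercept;
#' reaction times are independent of ID (Normal around \code{rtMeanMs} with a
#' right-hand advantage); miss and wrong-target flags are drawn from the
#' per-cell error rates. No-go trials carry \code{NA} reaction and movement
#' times. The block order (which width is tested in which block) is permuted
#' per subject; within a block every cue type occurs equally often in random
#' order. All randomness derives from per-subject child streams of the
#' config's master seed, so identical config and seed give identical output.
#'
#' @param design an [ExperimentDesign-class].
#' @param config a [GeneratorConfig-class].
#' @param blocksPerSubject number of blocks to simulate per subject (default
#'   the design's full block count; smaller values take the first blocks of
#'   the subject's permuted block order and are intended for reduced EEG
#'   runs).
#' @param subjects subject ids to simulate (default all).
#' @return data.frame with one row per trial: \code{subject}, \code{block},
#'   \code{trialInBlock}, \code{cueType}, \code{isNogo}, \code{hand},
#'   \code{width}, \code{amplitude}, \code{id}, \code{idLevel}, \code{rt},
#'   \code{mt} (ms, \code{NA} for no-go), \code{miss}, \code{wrongTarget},
#'   and the within-recording event times \code{cueOnsetMs}, \code{goOnsetMs},
#'   \code{liftMs}, \code{tapMs}.
#' @export
simulateBehaviour <- function(design, config,
                              blocksPerSubject = design@nBlocks,
                              subjects = seq_len(config@nSubjects)) {
  stopifnot(is(design, "ExperimentDesign"), is(config, "GeneratorConfig"))
  blocksPerSubject <- as.integer(blocksPerSubject)
  if (blocksPerSubject < 1L || blocksPerSubject > design@nBlocks)
    stop("blocksPerSubject must be between 1 and the design's block count")
  out <- lapply(subjects, function(s)
    .simulateSubjectBehaviour(design, config, s, blocksPerSubject))
  do.call(rbind, out)
}

.simulateSubjectBehaviour <- function(design, config, subject,
                                      blocksPerSubject) {
  eff <- .subjectEffects(config, subject)
  set.seed(.subjectSeed(config, subject, "behaviour"))
  nW <- length(design@widths)
  blockWidths <- sample(rep(design@widths, each = design@nBlocks / nW))
  blockWidths <- blockWidths[seq_len(blocksPerSubject)]
  reps <- design@trialsPerBlock / length(design@cueTypes)
  tm <- design@timing

  rows <- vector("list", blocksPerSubject)
  for (b in seq_len(blocksPerSubject)) {
    cueSeq <- sample(rep(design@cueTypes, reps))
    info <- .parseCueType(cueSeq, design, blockWidths[b])
    n <- length(cueSeq)
    act <- !info$isNogo
    rt <- mt <- rep(NA_real_, n)
    handAdj <- ifelse(info$hand == "right", -eff$rtHandOffset / 2,
                      eff$rtHandOffset / 2)
    rt[act] <- stats::rnorm(sum(act),
                            config@rtMeanMs + eff$rtIntercept + handAdj[act],
                            config@rtSdMs)
    mt[act] <- stats::rnorm(sum(act),
                            config@mtInterceptMs + eff$mtIntercept +
                              config@mtSlopeMsPerId * info$id[act],
                            config@mtNoiseSdMs)
    # keep event markers ordered and inside the trial period (tail
    # probability ~1e-6 at default parameters)
    rt[act] <- pmin(pmax(rt[act], 50), 1000)
    mt[act] <- pmin(pmax(mt[act], 50), 1200)

    widthRank <- match(blockWidths[b], design@widths)
    miss <- wrong <- rep(FALSE, n)
    pMiss <- .cellMissRate(config, design, widthRank, info$idLevel[act])
    pWrong <- config@wrongTargetRates[info$idLevel[act]]
    miss[act] <- stats::runif(sum(act)) < pMiss
    wrong[act] <- stats::runif(sum(act)) < pWrong
    miss[wrong] <- FALSE

    trialStart <- ((b - 1) * design@trialsPerBlock + seq_len(n) - 1) *
      tm$trialPeriodMs
    cueOnset <- trialStart + tm$fixationMs
    goOnset <- cueOnset + tm$foreperiodMs
    rows[[b]] <- data.frame(
      subject = subject, block = b, trialInBlock = seq_len(n),
      cueType = cueSeq, isNogo = info$isNogo, hand = info$hand,
      width = info$width, amplitude = info$amplitude, id = info$id,
      idLevel = info$idLevel, rt = rt, mt = mt,
      miss = miss, wrongTarget = wrong,
      cueOnsetMs = cueOnset, goOnsetMs = goOnset,
      liftMs = goOnset + rt, tapMs = goOnset + rt + mt,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
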
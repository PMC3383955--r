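#' @include erp-measures.R behaviour.R filter.R ocular.R simulate-recording.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Preprocess one subject's continuous recording into analysis-ready epochs
#'
#' The chain: fit the ocular-correction model on raw cue-locked epochs
#' (vertical EOG only by default; see [fitOcularModel()] for why horizontal
#' correction is left opt-in when the LRP is of interest),
#' apply it to the continuous recording, band-pass filter the continuous
#' recording (0.05-60 Hz zero-phase; filtering precedes epoching because the
#' high-pass time constant exceeds the epoch length), cut cue-locked
#' (-300 to 1500 ms, baseline the last 200 ms before the cue) and
#' response-locked (-800 to 200 ms around the stylus lift, baseline
#' -800 to -600 ms) epochs, and flag epochs whose peak-to-peak amplitude
#' exceeds 100 microvolts on any EEG channel.
#'
#' @param recording a [ContinuousRecording-class].
#' @param trials the subject's behavioural rows (condition metadata).
#' @param ocular fit and apply ocular correction (default \code{TRUE};
#'   disable for noise-free data whose EOG channels are flat).
#' @param eogChannels EOG channels entering the correction (default
#'   \code{"VEOG"}).
#' @param filter apply the band-pass (default \code{TRUE}).
#' @param hpHz,lpHz band-pass cutoffs.
#' @param rejectUv peak-to-peak rejection threshold.
#' @return List with \code{cueEpochs}, \code{liftEpochs} (both baselined
#'   [EpochSet-class]s), \code{ocularModel} (or \code{NULL}) and
#'   \code{counts} (epochs kept/rejected per set).
#' @export
preprocessRecording <- function(recording, trials, ocular = TRUE,
                                eogChannels = "VEOG",
                                filter = TRUE, hpHz = 0.05, lpHz = 60,
                                rejectUv = 100) {
  stopifnot(is(recording, "ContinuousRecording"))
  om <- NULL
  if (ocular) {
    raw <- .stage("ocular", epochRecording(recording, "cue",
                                           trials = trials))
    om <- .stage("ocular", fitOcularModel(raw, eogChannels = eogChannels))
    recording <- .stage("ocular", applyOcularModel(recording, om))
  }
  if (filter)
    recording <- .stage("filter", bandpass(recording, hpHz, lpHz))
  cue <- .stage("epoch", epochRecording(recording, "cue", trials = trials))
  cue <- .stage("reject", rejectArtifacts(cue, rejectUv))
  cue <- .stage("baseline", baselineCorrect(cue, c(-200, 0)))
  lift <- .stage("epoch", epochRecording(recording, "lift", trials = trials))
  lift <- .stage("reject", rejectArtifacts(lift, rejectUv))
  lift <- .stage("baseline", baselineCorrect(lift, c(-800, -600)))
  counts <- list(
    cue = c(kept = sum(!rejected(cue)), rejected = sum(rejected(cue))),
    lift = c(kept = sum(!rejected(lift)), rejected = sum(rejected(lift))))
  list(cueEpochs = cue, liftEpochs = lift, ocularModel = om,
       counts = counts)
}

# analysis-usable epochs: accepted, correct responses
.usableEpochs <- function(epochs) {
  cond <- epochs@conditions
  keep <- !epochs@rejected
  for (fl in intersect(c("miss", "wrongTarget"), names(cond)))
    keep <- keep & !cond[[fl]]
  epochs[keep]
}

#' Derive one subject's ERP measures from preprocessed epochs
#'
#' Computes, per width x ID cell (hands pooled, incorrect responses and
#' rejected epochs excluded): the posterior N2/P3b ROI window mean, the
#' motor CNV (action minus no-go), the lateralized HEOG, and the LRP from
#' the response-locked averages of the two hands.
#'
#' @param prep output of [preprocessRecording()].
#' @return data.frame of measures: \code{width}, \code{id},
#'   \code{amplitude}, \code{measure}, \code{value}.
#' @export
subjectErpMeasures <- function(prep) {
  cue <- .usableEpochs(prep$cueEpochs)
  cond <- cue@conditions
  cond$cell <- ifelse(cond$isNogo, "nogo", paste0("w", cond$width,
                                                  "_id", cond$id))
  cue@conditions <- cond
  cellErps <- .stage("average", averageEpochs(cue,
    by = c("cell", "width", "id", "isNogo")))

  n2 <- roiWindowMean(cellErps)
  n2 <- n2[!n2$isNogo, c("width", "id", "value", "measure")]
  cnv <- motorCNV(cellErps, labelColumn = "cell")
  cnv <- cnv[, c("width", "id", "value", "measure")]
  lheog <- lateralizedHEOG(cue)[, c("width", "id", "value", "measure")]

  lift <- .usableEpochs(prep$liftEpochs)
  lrp <- NULL
  if (dim(lift@data)[1] > 0) {
    byHand <- lapply(c("left", "right"), function(h) {
      sub <- lift[lift@conditions$hand == h]
      if (dim(sub@data)[1] == 0) return(NULL)
      averageEpochs(sub, by = c("width", "id"))
    })
    if (!is.null(byHand[[1]]) && !is.null(byHand[[2]])) {
      lKey <- paste(byHand[[1]]@conditions$width, byHand[[1]]@conditions$id)
      rKey <- paste(byHand[[2]]@conditions$width, byHand[[2]]@conditions$id)
      common <- intersect(lKey, rKey)
      lrp <- lrpAmplitude(byHand[[1]][lKey %in% common],
                          byHand[[2]][rKey %in% common])
      lrp <- lrp[, c("width", "id", "value", "measure")]
    }
  }
  out <- rbind(n2, cnv, lheog, lrp)
  out$amplitude <- out$width * 2^out$id / 2
  rownames(out) <- NULL
  out
}

.regList <- function(fit) {
  list(slope = fit@slope, intercept = fit@intercept, r2 = fit@r2,
       f = fit@fStat, dfNum = fit@dfNum, dfDen = fit@dfDen, p = fit@p,
       n = fit@n, slopeCI = slopeCI(fit))
}

.grandMeasures <- function(measures) {
  key <- paste(measures$measure, measures$width, measures$id, sep = "|")
  rows <- lapply(unique(key), function(g) {
    sub <- measures[key == g, , drop = FALSE]
    data.frame(measure = sub$measure[1], width = sub$width[1],
               id = sub$id[1], amplitude = sub$amplitude[1],
               nSubjects = nrow(sub), value = mean(sub$value))
  })
  out <- do.call(rbind, rows)
  out[order(out$measure, out$width, out$id), ]
}

#' Run the full synthetic study and analysis pipeline
#'
#' Simulates the experiment (behaviour and, optionally, continuous
#' recordings) for every subject, runs the preprocessing and measurement
#' chain, and assembles a single report holding every behavioural and
#' electrophysiological result: trimmed-trial counts, RT/MT cell summaries,
#' the error table, the MT regressions on ID and amplitude, the RT hand
#' t-test, the grand-average ERP measures, and the six ERP regressions
#' (posterior N2/P3b, lateralized HEOG, motor CNV and LRP on ID and on
#' amplitude, the latter two serving as null checks). The report is
#' deterministic: identical design, config and seed give identical output.
#'
#' @param design an [ExperimentDesign-class] (default [buildDesign()]).
#' @param config a [GeneratorConfig-class] (default [generatorConfig()]).
#' @param blocksPerSubject blocks simulated per subject (default the full
#'   design for behaviour-only runs; EEG runs typically use a reduced block
#'   count).
#' @param recordings simulate and analyse EEG (default \code{TRUE}).
#' @param ocular,filter preprocessing switches (see
#'   [preprocessRecording()]).
#' @param verbose print per-stage progress.
#' @return A nested report list (JSON-serializable).
#' @export
runPipeline <- function(design = buildDesign(), config = generatorConfig(),
                        blocksPerSubject = if (recordings) 2L else
                          design@nBlocks,
                        recordings = TRUE, ocular = TRUE, filter = TRUE,
                        verbose = FALSE) {
  trials <- .stage("simulate", simulateBehaviour(design, config,
                                                 blocksPerSubject))
  trim <- .stage("behaviour", trimTrials(trials))
  kept <- trim$kept
  behaviour <- list(
    nTrials = nrow(trials),
    nTrimmed = nrow(trim$removed),
    cells = cellSummaries(kept),
    mtById = .regList(.stage("behaviour", fittsRegression(kept, "id"))),
    mtByAmplitude = .regList(.stage("behaviour",
                                    fittsRegression(kept, "amplitude"))),
    rtHandTTest = .stage("behaviour", {
      hm <- subjectHandMeans(kept)
      if (nrow(hm) >= 2) handTTest(hm$left, hm$right) else NULL
    }),
    errors = .stage("behaviour", errorTable(trials)))

  erp <- NULL
  if (recordings) {
    measures <- vector("list", config@nSubjects)
    counts <- vector("list", config@nSubjects)
    for (s in seq_len(config@nSubjects)) {
      if (verbose) message("subject ", s, "/", config@nSubjects)
      rec <- .stage("simulate",
                    simulateRecording(design,
                                      trials[trials$subject == s, ], config))
      prep <- preprocessRecording(rec, trials[trials$subject == s, ],
                                  ocular = ocular, filter = filter)
      m <- .stage("measures", subjectErpMeasures(prep))
      m$subject <- s
      measures[[s]] <- m
      counts[[s]] <- prep$counts
    }
    measures <- do.call(rbind, measures)
    grand <- .grandMeasures(measures)
    regs <- list()
    for (ms in c("n2p3b", "lheog", "motor_cnv", "lrp")) {
      sub <- grand[grand$measure == ms, , drop = FALSE]
      for (pred in c("id", "amplitude"))
        regs[[paste0(ms, "_", pred)]] <-
          .regList(.stage("regression", erpRegression(sub, pred)))
    }
    erp <- list(
      epochCounts = list(
        cueKept = sum(vapply(counts, function(x) x$cue[["kept"]], 0)),
        cueRejected = sum(vapply(counts, function(x) x$cue[["rejected"]], 0)),
        liftKept = sum(vapply(counts, function(x) x$lift[["kept"]], 0)),
        liftRejected = sum(vapply(counts,
                                  function(x) x$lift[["rejected"]], 0))),
      grandMeasures = grand,
      regressions = regs,
      subjectMeasures = measures)
  }

  list(
    provenance = list(
      package = "fittsERP",
      version = as.character(utils::packageVersion("fittsERP")),
      seed = config@seed, nSubjects = config@nSubjects,
      blocksPerSubject = as.integer(blocksPerSubject),
      fsHz = config@fsHz),
    design = list(trialsPerBlock = design@trialsPerBlock,
                  nBlocks = design@nBlocks,
                  cueTypeProbability = cueTypeProbability(design),
                  blockDurationS = design@blockDurationS),
    behaviour = behaviour,
    erp = erp)
}

#' Write a pipeline report to JSON
#'
#' @param report output of [runPipeline()].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
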
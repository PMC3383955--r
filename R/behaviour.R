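#' @include stats.R
NULL

#' Extract reaction and movement times from event markers
#'
#' Walks the marker stream of a recording: for every go-trial, the reaction
#' time is the interval from the go marker to the stylus-lift marker and the
#' movement time the interval from the lift to the subsequent tap, both
#' converted from sample indices to ms. Trials with missing or disordered
#' markers (e.g. a lift before the go: anticipation) are flagged invalid and
#' excluded with a logged reason. No-go cues yield no row.
#'
#' @param events event data.frame (\code{sample_index}, \code{label}) or a
#'   [ContinuousRecording-class].
#' @param fsHz sampling rate (taken from the recording if one is given).
#' @return data.frame with one row per directional-cue trial: \code{label}
#'   (the cue), \code{cueSample}, \code{rt}, \code{mt} (ms; \code{NA} when
#'   invalid) and \code{valid}.
#' @export
extractRtMt <- function(events, fsHz = NULL) {
  if (is(events, "ContinuousRecording")) {
    fsHz <- events@fsHz
    events <- eventTable(events)
  }
  if (is.null(fsHz)) stop("extractRtMt: fsHz required")
  lab <- events$label
  smp <- events$sample_index
  cueIdx <- which(grepl("^cue_", lab))
  if (!length(cueIdx))
    return(data.frame(label = character(), cueSample = integer(),
                      rt = numeric(), mt = numeric(), valid = logical()))
  bound <- c(which(grepl("^cue_", lab) | lab == "nogo"), length(lab) + 1L)
  out <- lapply(cueIdx, function(i) {
    nxt <- bound[bound > i][1]                 # start of the next trial
    span <- if (is.na(nxt)) integer() else (i + 1L):(nxt - 1L)
    span <- span[span <= length(lab)]
    go <- span[lab[span] == "go"][1]
    lift <- span[lab[span] == "lift"][1]
    tap <- span[lab[span] == "tap"][1]
    valid <- !is.na(go) && !is.na(lift) && !is.na(tap) &&
      smp[go] < smp[lift] && smp[lift] < smp[tap]
    data.frame(label = lab[i], cueSample = smp[i],
               rt = if (valid) (smp[lift] - smp[go]) * 1000 / fsHz else
                 NA_real_,
               mt = if (valid) (smp[tap] - smp[lift]) * 1000 / fsHz else
                 NA_real_,
               valid = valid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(!out$valid))
    message("extractRtMt: ", sum(!out$valid),
            " trial(s) with missing or disordered markers excluded")
  out
}

#' Trim reaction/movement-time outliers
#'
#' Two-stage trial removal, mirroring standard speed-accuracy practice:
#' first an absolute floor (any trial whose RT or MT is below
#' \code{floorMs}), then a single-pass SD rule that removes trials deviating
#' from their condition mean by more than \code{sdMult} standard deviations,
#' with mean and SD computed on the floor-surviving trials of that
#' condition. The rule is applied to RT and MT separately; conditions are
#' subject x hand x width x ID cells. No-go trials pass through untouched.
#'
#' @param trials behavioural trial table.
#' @param floorMs absolute minimum in ms (default 100).
#' @param sdMult SD multiplier (default 2).
#' @return List with \code{kept} and \code{removed} data.frames; the
#'   \code{removed} table carries a \code{trimReason} column.
#' @export
trimTrials <- function(trials, floorMs = 100, sdMult = 2) {
  if (floorMs < 0) stop("trimTrials: floorMs must be non-negative")
  if (sdMult <= 0) stop("trimTrials: sdMult must be positive")
  nogo <- trials[trials$isNogo, , drop = FALSE]
  act <- trials[!trials$isNogo, , drop = FALSE]
  reason <- rep(NA_character_, nrow(act))
  belowFloor <- act$rt < floorMs | act$mt < floorMs
  reason[belowFloor] <- "floor"
  key <- paste(act$subject, act$hand, act$width, act$id, sep = "|")
  for (g in unique(key)) {
    idx <- which(key == g & !belowFloor)
    if (length(idx) < 3L) next
    for (v in c("rt", "mt")) {
      x <- act[[v]][idx]
      m <- mean(x); s <- stats::sd(x)
      if (s > 0) {
        out <- abs(x - m) > sdMult * s
        reason[idx[out & is.na(reason[idx])]] <- paste0(v, "_sd")
      }
    }
  }
  removed <- act[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$trimReason <- reason[!is.na(reason)]
  kept <- rbind(act[is.na(reason), , drop = FALSE], nogo)
  kept <- kept[order(kept$subject, kept$block, kept$trialInBlock), ,
               drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Per-condition behavioural cell summaries
#'
#' Means and SDs of RT and MT plus error counts for every width x ID cell
#' (optionally split by hand and/or subject).
#'
#' @param trials behavioural trial table (trimmed or not).
#' @param by grouping columns (default \code{c("width", "id")}: hands
#'   pooled).
#' @return data.frame with \code{n}, \code{meanRt}, \code{sdRt},
#'   \code{meanMt}, \code{sdMt}, \code{missRate}, \code{wrongTargetRate} per
#'   cell. Miss and wrong-target trials are excluded from the RT/MT means
#'   (incorrect responses are removed before averaging) but counted in the
#'   rates.
#' @export
cellSummaries <- function(trials, by = c("width", "id")) {
  act <- trials[!trials$isNogo, , drop = FALSE]
  key <- do.call(paste, c(act[by], sep = "|"))
  groups <- unique(key)
  rows <- lapply(groups, function(g) {
    cell <- act[key == g, , drop = FALSE]
    good <- !cell$miss & !cell$wrongTarget
    out <- cell[1, by, drop = FALSE]
    out$n <- nrow(cell)
    out$meanRt <- mean(cell$rt[good])
    out$sdRt <- stats::sd(cell$rt[good])
    out$meanMt <- mean(cell$mt[good])
    out$sdMt <- stats::sd(cell$mt[good])
    out$missRate <- mean(cell$miss)
    out$wrongTargetRate <- mean(cell$wrongTarget)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fitts regression of movement time on ID or amplitude
#'
#' Ordinary least squares of condition-mean movement time on the index of
#' difficulty (or, for comparison, on movement amplitude), fitted on the
#' width x ID condition means with hands pooled — the 9-point structure of
#' the factorial design. Per-trial fitting is available behind a flag.
#'
#' @param trials behavioural trial table (ideally trimmed); miss and
#'   wrong-target trials are excluded.
#' @param predictor \code{"id"} or \code{"amplitude"}.
#' @param perTrial fit on single trials instead of cell means (default
#'   \code{FALSE}).
#' @return A [RegressionResult-class].
#' @export
fittsRegression <- function(trials, predictor = c("id", "amplitude"),
                            perTrial = FALSE) {
  predictor <- match.arg(predictor)
  act <- trials[!trials$isNogo & !trials$miss & !trials$wrongTarget, ,
                drop = FALSE]
  if (perTrial)
    return(olsFit(act[[predictor]], act$mt, predictor))
  cells <- cellSummaries(act)
  cells$amplitude <- cells$width * 2^cells$id / 2
  if (length(unique(cells[[predictor]])) < 3L)
    stop("fittsRegression: need >= 3 distinct predictor values")
  olsFit(cells[[predictor]], cells$meanMt, predictor)
}

#' Tabulate miss and wrong-target error rates
#'
#' Miss rates per width x target-distance cell (the proportion of trials
#' whose tap landed outside the designated target) and wrong-target rates
#' per cue/arrow size (ID level).
#'
#' @param trials behavioural trial table (untrimmed).
#' @return List with \code{missByCell} (width, id, amplitude, idLevel, n,
#'   missRate) and \code{wrongByCue} (idLevel, n, wrongTargetRate).
#' @export
errorTable <- function(trials) {
  act <- trials[!trials$isNogo, , drop = FALSE]
  byCell <- cellSummaries(act, by = c("width", "id"))
  cells <- act[!duplicated(paste(act$width, act$id)),
               c("width", "id", "amplitude", "idLevel")]
  missByCell <- merge(cells, byCell[, c("width", "id", "n", "missRate")],
                      by = c("width", "id"))
  missByCell <- missByCell[order(missByCell$width, missByCell$id), ]
  rownames(missByCell) <- NULL
  wrong <- lapply(sort(unique(act$idLevel)), function(k) {
    sel <- act$idLevel == k
    data.frame(idLevel = k, n = sum(sel),
               wrongTargetRate = mean(act$wrongTarget[sel]))
  })
  list(missByCell = missByCell, wrongByCue = do.call(rbind, wrong))
}

#' Per-subject mean reaction times by hand
#'
#' Convenience reduction feeding [handTTest()]: mean RT per subject for each
#' hand, after excluding miss/wrong-target trials.
#'
#' @param trials behavioural trial table (ideally trimmed).
#' @return data.frame with \code{subject}, \code{left}, \code{right}.
#' @export
subjectHandMeans <- function(trials) {
  act <- trials[!trials$isNogo & !trials$miss & !trials$wrongTarget, ,
                drop = FALSE]
  subjects <- sort(unique(act$subject))
  out <- data.frame(subject = subjects)
  for (h in c("left", "right"))
    out[[h]] <- vapply(subjects, function(s)
      mean(act$rt[act$subject == s & act$hand == h]), 0)
  out
}
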
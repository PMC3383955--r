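#' @include simulate-behaviour.R
NULL

# 1/f^exponent noise via spectral shaping of white Gaussian noise,
# normalized to unit SD before scaling.
.pinkNoise <- function(n, exponent) {
  if (n < 4L) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freq <- c(1, seq_len(n - 1))             # avoid dividing by zero at DC
  freq <- pmin(freq, n - freq + 1)         # symmetric (two-sided spectrum)
  f <- f * (1 / freq^(exponent / 2))
  f[1] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Gaussian bump, unit peak, centred at centerMs with width sdMs
.gaussBump <- function(tMs, centerMs, sdMs) {
  exp(-((tMs - centerMs)^2) / (2 * sdMs^2))
}

# mean of the unit posterior bump over the measurement window on the epoch
# sample grid; used to invert the window-mean law exactly
.bumpWindowGain <- function(fs, windowMs = c(310, 370), centerMs = 340,
                            sdMs = 50) {
  tt <- seq(0, 2000, by = 1000 / fs)
  sel <- tt >= windowMs[1] & tt < windowMs[2]
  mean(.gaussBump(tt[sel], centerMs, sdMs))
}

# mean of the unit HEOG sigmoid over [250, 450) ms after go onset
.heogWindowGain <- function(fs, windowMs = c(250, 450), centerMs = 120,
                            slopeMs = 30) {
  tt <- seq(0, 1000, by = 1000 / fs)
  sel <- tt >= windowMs[1] & tt < windowMs[2]
  mean(1 / (1 + exp(-(tt[sel] - centerMs) / slopeMs)))
}

#' Simulate the continuous EEG/EOG recording of one subject
#'
#' Builds a [ContinuousRecording-class] for the trials of a single subject:
#' 1/f plus white background noise on every channel, Poisson blink artifacts
#' on VEOG propagated to the scalp by the configured coefficients, and the
#' per-trial components the analysis targets: (i) a cue-locked posterior
#' Gaussian component on the parieto-occipital ROI whose window mean over
#' 310-370 ms after cue onset equals \code{erpInterceptUv +
#' erpSlopeUvPerId * ID} (plus the subject's random intercept); (ii) an
#' anticipatory CNV ramp on centro-parietal channels shared by action and
#' no-go trials, plus an ID-independent motor CNV ramp on action trials only,
#' ending at go onset; (iii) an ID-independent lateralized motor potential
#' contralateral to the responding hand, peaking at the stylus-lift marker;
#' (iv) a horizontal EOG step after the go signal whose lateralized mean over
#' 250-450 ms after go onset equals \code{heogInterceptUv +
#' heogSlopeUvPerCm * amplitude}, negative for gaze toward the target after
#' sign alignment. Event markers are written for cue (label
#' \code{cue_<width>_<id>_<hand>} or \code{nogo}), go, stylus lift and target
#' tap.
#'
#' @param design an [ExperimentDesign-class].
#' @param trials the subject's rows from [simulateBehaviour()] (a single
#'   subject id).
#' @param config a [GeneratorConfig-class].
#' @return A [ContinuousRecording-class].
#' @export
simulateRecording <- function(design, trials, config) {
  stopifnot(is(design, "ExperimentDesign"), is(config, "GeneratorConfig"))
  if (length(unique(trials$subject)) != 1L)
    stop("simulateRecording expects the trials of exactly one subject")
  if (config@fsHz < 128)
    stop("fsHz too low for the requested components (need >= 128 Hz)")
  fs <- config@fsHz
  subject <- trials$subject[1]
  eff <- .subjectEffects(config, subject)
  set.seed(.subjectSeed(config, subject, "recording"))

  labels <- config@channelLabels
  eeg <- setdiff(labels, c("VEOG", "HEOG"))
  nCh <- length(labels)
  tm <- design@timing
  nSamples <- nrow(trials) * tm$trialPeriodMs / 1000 * fs
  if (abs(nSamples - round(nSamples)) > 1e-9)
    stop("trial period must be a whole number of samples")
  nSamples <- as.integer(round(nSamples))

  dat <- matrix(0, nCh, nSamples, dimnames = list(labels, NULL))
  # background noise, channel by channel in montage order
  for (ch in seq_len(nCh)) {
    if (config@pinkSdUv > 0)
      dat[ch, ] <- dat[ch, ] + config@pinkSdUv *
        .pinkNoise(nSamples, config@pinkExponent)
    if (config@whiteSdUv > 0)
      dat[ch, ] <- dat[ch, ] + stats::rnorm(nSamples, 0, config@whiteSdUv)
  }

  ms2smp <- function(ms) as.integer(round(ms * fs / 1000))  # 0-based

  # blink artifacts: Poisson events, Gaussian shape (SD 50 ms) on VEOG,
  # propagated to the scalp
  if (config@blinkRateHz > 0 && config@blinkAmpUv > 0) {
    durS <- nSamples / fs
    nBlink <- stats::rpois(1, config@blinkRateHz * durS)
    if (nBlink > 0) {
      tBlink <- sort(stats::runif(nBlink, 0.3, durS - 0.3))
      aBlink <- stats::rnorm(nBlink, config@blinkAmpUv,
                             0.1 * config@blinkAmpUv)
      blinkTrace <- numeric(nSamples)
      half <- ms2smp(200)
      for (i in seq_len(nBlink)) {
        c0 <- ms2smp(tBlink[i] * 1000)
        idx <- max(0L, c0 - half):min(nSamples - 1L, c0 + half)
        blinkTrace[idx + 1L] <- blinkTrace[idx + 1L] +
          aBlink[i] * .gaussBump(idx * 1000 / fs, tBlink[i] * 1000, 50)
      }
      dat["VEOG", ] <- dat["VEOG", ] + blinkTrace
      for (ch in eeg)
        dat[ch, ] <- dat[ch, ] + config@propagation$veog[[ch]] * blinkTrace
    }
  }

  roi <- intersect(c("Pz", "P1", "P2", "POz", "PO3", "PO4"), labels)
  cnvMotorCh <- intersect(c("Cz", "FCz", "CPz", "C1", "C2"), labels)
  cnvAnticipCh <- intersect(c("Cz", "FCz", "CPz", "C1", "C2", "C3", "C4"),
                            labels)
  bumpGain <- .bumpWindowGain(fs)
  heogGain <- .heogWindowGain(fs)
  heogTask <- numeric(nSamples)

  addTo <- function(chs, idx, values) {
    keep <- idx >= 0L & idx < nSamples
    for (ch in chs)
      dat[ch, idx[keep] + 1L] <<- dat[ch, idx[keep] + 1L] + values[keep]
  }

  events <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    cueSmp <- ms2smp(tr$cueOnsetMs)
    goSmp <- ms2smp(tr$goOnsetMs)
    cueLabel <- if (tr$isNogo) "nogo" else
      sprintf("cue_%g_%g_%s", tr$width, tr$id, tr$hand)
    ev <- data.frame(sample_index = c(cueSmp, goSmp),
                     label = c(cueLabel, "go"))

    # anticipatory CNV: linear ramp from cue+200 ms to go onset, decaying
    # over 300 ms afterwards; shared by action and no-go trials
    rampIdx <- (cueSmp + ms2smp(200)):(goSmp + ms2smp(300))
    tRel <- (rampIdx - cueSmp) * 1000 / fs
    fpMs <- tm$foreperiodMs
    ramp <- ifelse(tRel <= fpMs, (tRel - 200) / (fpMs - 200),
                   pmax(0, 1 - (tRel - fpMs) / 300))
    if (config@cnvAnticipUv != 0)
      addTo(cnvAnticipCh, rampIdx, -config@cnvAnticipUv * ramp)

    if (!tr$isNogo) {
      liftSmp <- ms2smp(tr$liftMs)
      tapSmp <- ms2smp(tr$tapMs)
      ev <- rbind(ev, data.frame(sample_index = c(liftSmp, tapSmp),
                                 label = c("lift", "tap")))

      # posterior N2/P3b: Gaussian bump on the ROI, window mean equals the
      # linear law in ID
      amp <- (config@erpInterceptUv + config@erpSlopeUvPerId * tr$id +
                eff$erpIntercept) / bumpGain
      bumpIdx <- (cueSmp + ms2smp(100)):(cueSmp + ms2smp(600))
      addTo(roi, bumpIdx,
            amp * .gaussBump((bumpIdx - cueSmp) * 1000 / fs, 340, 50))

      # motor CNV: ID-independent ramp on the measurement electrodes, held
      # from go onset until the stylus lift, then decaying over 300 ms
      cnvA <- config@cnvAmpUv + eff$cnvAmp
      if (cnvA != 0) {
        mIdx <- (cueSmp + ms2smp(200)):(liftSmp + ms2smp(300))
        tRelM <- (mIdx - cueSmp) * 1000 / fs
        liftRel <- (liftSmp - cueSmp) * 1000 / fs
        mRamp <- ifelse(tRelM <= fpMs, (tRelM - 200) / (fpMs - 200),
                        ifelse(tRelM <= liftRel, 1,
                               pmax(0, 1 - (tRelM - liftRel) / 300)))
        addTo(cnvMotorCh, mIdx, -cnvA * mRamp)
      }

      # LRP: ID-independent negative ramp contralateral to the responding
      # hand, peaking at the lift marker
      lrpA <- config@lrpAmpUv + eff$lrpAmp
      if (lrpA != 0) {
        contra <- if (tr$hand == "right") c("C1", "C3") else c("C2", "C4")
        lIdx <- (liftSmp - ms2smp(400)):(liftSmp + ms2smp(200))
        tRelL <- (lIdx - liftSmp) * 1000 / fs
        lRamp <- ifelse(tRelL <= 0, (tRelL + 400) / 400,
                        pmax(0, 1 - tRelL / 200))
        addTo(intersect(contra, labels), lIdx, -lrpA * lRamp)
      }

      # horizontal EOG: sigmoid step after go, plateau through the
      # measurement window, returning to zero after the tap; gaze toward the
      # target; left targets flip the sign
      v <- (config@heogInterceptUv + config@heogSlopeUvPerCm * tr$amplitude +
              eff$heogIntercept) / heogGain
      side <- if (tr$hand == "left") -1 else 1
      hIdx <- goSmp:(tapSmp + ms2smp(600))
      tRelH <- (hIdx - goSmp) * 1000 / fs
      tapRel <- (tapSmp - goSmp) * 1000 / fs
      sig <- 1 / (1 + exp(-(tRelH - 120) / 30))
      fall <- pmax(0, pmin(1, 1 - (tRelH - tapRel - 200) / 300))
      keep <- hIdx >= 0L & hIdx < nSamples
      heogTask[hIdx[keep] + 1L] <- heogTask[hIdx[keep] + 1L] +
        (side * v * sig * fall)[keep]
    }
    events[[i]] <- ev
  }

  dat["HEOG", ] <- dat["HEOG", ] + heogTask
  for (ch in eeg)
    dat[ch, ] <- dat[ch, ] + config@propagation$heog[[ch]] * heogTask

  events <- do.call(rbind, events)
  events <- events[order(events$sample_index), ]
  rownames(events) <- NULL
  new("ContinuousRecording", fsHz = fs, channelLabels = labels, data = dat,
      events = events)
}

#' Simulate a full study: behaviour plus one recording per subject
#'
#' Convenience wrapper running [simulateBehaviour()] and, optionally,
#' [simulateRecording()] for every subject.
#'
#' @param design an [ExperimentDesign-class].
#' @param config a [GeneratorConfig-class].
#' @param blocksPerSubject blocks per subject (see [simulateBehaviour()]).
#' @param recordings if \code{FALSE}, only behaviour is generated.
#' @return List with \code{trials} (all subjects) and \code{recordings}
#'   (named list of [ContinuousRecording-class], or \code{NULL}).
#' @export
simulateStudy <- function(design, config,
                          blocksPerSubject = design@nBlocks,
                          recordings = TRUE) {
  trials <- simulateBehaviour(design, config, blocksPerSubject)
  recs <- NULL
  if (recordings) {
    recs <- lapply(seq_len(config@nSubjects), function(s)
      simulateRecording(design, trials[trials$subject == s, ], config))
    names(recs) <- paste0("subject", seq_len(config@nSubjects))
  }
  list(trials = trials, recordings = recs)
}
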
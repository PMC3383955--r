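# Shared fixtures for the test suite.

# A tiny continuous recording with deterministic data and a regular event
# grid: nTrials trials of 2 s each at fs Hz, cue at +0.5 s, go at +1.5 s
# within each trial (matching the 1000 ms foreperiod).
toyRecording <- function(fs = 100, nTrials = 4, labels = c("Cz", "Pz", "VEOG",
                                                           "HEOG"),
                         cueLabels = rep("cue_2_3_right", nTrials)) {
  n <- as.integer(nTrials * 2 * fs)
  dat <- matrix(seq_len(length(labels) * n) / 1000, length(labels), n,
                dimnames = list(labels, NULL))
  ev <- do.call(rbind, lapply(seq_len(nTrials), function(i) {
    t0 <- (i - 1) * 2 * fs
    data.frame(sample_index = as.integer(t0 + c(0.5, 1.5) * fs),
               label = c(cueLabels[i], "go"))
  }))
  new("ContinuousRecording", fsHz = fs, channelLabels = labels, data = dat,
      events = ev)
}

# An EpochSet built directly from a data array, with minimal but valid
# metadata. data: epochs x channels x samples.
toyEpochs <- function(data, labels, fs = 100, windowMs = NULL,
                      conditions = NULL, lockEvent = "cue") {
  nT <- dim(data)[3]
  if (is.null(windowMs)) windowMs <- c(0, nT * 1000 / fs)
  if (is.null(conditions))
    conditions <- data.frame(label = rep("cue_2_3_right", dim(data)[1]),
                             stringsAsFactors = FALSE)
  new("EpochSet", data = data, fsHz = fs, channelLabels = labels,
      timesMs = windowMs[1] + (0:(nT - 1)) * 1000 / fs,
      lockEvent = lockEvent, windowMs = as.numeric(windowMs),
      baselineMs = numeric(), conditions = conditions,
      rejected = rep(FALSE, dim(data)[1]),
      rejectReason = rep("", dim(data)[1]))
}

# A minimal behavioural trial table for one subject x hand x cell.
makeTrials <- function(rt, mt, subject = 1L, hand = "right", width = 2,
                       id = 3) {
  n <- max(length(rt), length(mt))
  rt <- rep_len(rt, n); mt <- rep_len(mt, n)
  data.frame(subject = subject, block = 1L, trialInBlock = seq_len(n),
             cueType = "id2_right", isNogo = FALSE, hand = hand,
             width = width, amplitude = width * 2^id / 2, id = id,
             idLevel = 2L, rt = rt, mt = mt, miss = FALSE,
             wrongTarget = FALSE, cueOnsetMs = 0, goOnsetMs = 1000,
             liftMs = 1000 + rt, tapMs = 1000 + rt + mt)
}

# Epochs with known EOG-to-EEG propagation: EOG channels carry trial-varying
# artifact waveforms, EEG channels receive beta * EOG plus independent noise
# plus a condition-constant evoked signal.
makeOcularEpochs <- function(nEp = 24, nT = 120, betaV = c(Cz = 0.25,
                                                           Pz = 0.08),
                             betaH = c(Cz = 0.04, Pz = -0.02), fs = 100,
                             seed = 13) {
  set.seed(seed)
  labels <- c("Cz", "Pz", "VEOG", "HEOG")
  cond <- rep(c("cue_2_3_left", "cue_2_3_right"), length.out = nEp)
  evoked <- outer(c(Cz = 3, Pz = -2), sin(seq(0, pi, length.out = nT)))
  dat <- array(0, c(nEp, 4, nT))
  for (e in seq_len(nEp)) {
    veog <- rnorm(1, 120, 40) * exp(-((seq_len(nT) - 60)^2) / 200) +
      rnorm(nT, 0, 3)
    heog <- rnorm(1, 0, 30) * plogis((seq_len(nT) - 70) / 5) + rnorm(nT, 0, 3)
    dat[e, 3, ] <- veog
    dat[e, 4, ] <- heog
    for (ch in 1:2)
      dat[e, ch, ] <- evoked[ch, ] * (1 + 0.1 * (cond[e] == "cue_2_3_right")) +
        betaV[ch] * veog + betaH[ch] * heog + rnorm(nT, 0, 1)
  }
  toyEpochs(dat, labels, fs = fs,
            conditions = data.frame(label = cond, stringsAsFactors = FALSE))
}

# An ErpSet built directly from a conditions x channels x samples array.
toyErps <- function(data, labels, conditions, fs = 100, t0Ms = 0,
                    lockEvent = "cue") {
  nT <- dim(data)[3]
  new("ErpSet", data = data, conditions = conditions, fsHz = fs,
      channelLabels = labels, timesMs = t0Ms + (0:(nT - 1)) * 1000 / fs,
      lockEvent = lockEvent)
}
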
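test_that("recordings are deterministic and carry ordered markers", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 1L, fsHz = 200, seed = 8L)
  tr <- simulateBehaviour(d, cfg, 1L)
  a <- simulateRecording(d, tr, cfg)
  b <- simulateRecording(d, tr, cfg)
  expect_identical(signalData(a), signalData(b))
  expect_identical(eventTable(a), eventTable(b))
  expect_equal(fsHz(a), 200)
  expect_identical(channelLabels(a), cfg@channelLabels)
  expect_identical(ncol(signalData(a)), 63L * 4L * 200L)
  ev <- eventTable(a)
  expect_true(all(diff(ev$sample_index) > 0))
  # every go-trial contributes cue/go/lift/tap, no-go trials cue/go only
  expect_equal(sum(ev$label == "go"), 63)
  expect_equal(sum(ev$label == "lift"), sum(!tr$isNogo))
  expect_equal(sum(ev$label == "nogo"), sum(tr$isNogo))
})

test_that("recording markers agree with the behavioural table", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 1L, fsHz = 200, seed = 12L)
  tr <- simulateBehaviour(d, cfg, 1L)
  rec <- simulateRecording(d, tr, cfg)
  got <- extractRtMt(rec)
  act <- tr[!tr$isNogo, ]
  # rounding to the 5 ms sample grid bounds the marker error
  expect_lt(max(abs(got$rt - act$rt)), 5.001)
  expect_lt(max(abs(got$mt - act$mt)), 5.001)
  expect_true(all(got$valid))
})

test_that("simulateRecording validates its input", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 2L, seed = 1L)
  tr <- simulateBehaviour(d, cfg, 1L)
  expect_error(simulateRecording(d, tr, cfg), "exactly one subject")
  low <- generatorConfig(nSubjects = 1L, fsHz = 64)
  expect_error(simulateRecording(d, tr[tr$subject == 1, ], low),
               ">= 128 Hz")
})

test_that("noise-free recordings contain exactly the programmed components", {
  d <- buildDesign()
  cfg <- noiselessConfig(nSubjects = 1L, fsHz = 200, seed = 3L)
  tr <- simulateBehaviour(d, cfg, 1L)
  rec <- simulateRecording(d, tr, cfg)
  dat <- signalData(rec)
  # VEOG is flat without blinks; HEOG carries only the task saccades
  expect_true(all(dat["VEOG", ] == 0))
  expect_gt(max(abs(dat["HEOG", ])), 100)
  # HEOG deflection is negative for right targets, positive for left
  fs <- 200
  act <- tr[!tr$isNogo, ]
  mid <- as.integer(round((act$goOnsetMs + 300) * fs / 1000)) + 1L
  sgn <- ifelse(act$hand == "left", 1, -1)
  expect_true(all(sgn * dat["HEOG", mid] > 0))
  # posterior bump appears on the ROI but not on Cz pre-go
  cueWin <- as.integer(round(act$cueOnsetMs[1] * fs / 1000)) + (60:80)
  expect_gt(max(abs(dat["Pz", cueWin])), 0)
})

test_that("simulateStudy bundles trials with per-subject recordings", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 2L, fsHz = 200, seed = 10L)
  st <- simulateStudy(d, cfg, blocksPerSubject = 1L)
  expect_named(st, c("trials", "recordings"))
  expect_length(st$recordings, 2L)
  expect_s4_class(st$recordings$subject1, "ContinuousRecording")
  expect_identical(sort(unique(st$trials$subject)), c(1L, 2L))
  behavOnly <- simulateStudy(d, cfg, blocksPerSubject = 1L,
                             recordings = FALSE)
  expect_null(behavOnly$recordings)
})
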
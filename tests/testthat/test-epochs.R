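test_that("epoching extracts the right samples with a half-open window", {
  fs <- 100
  n <- 400
  rec <- new("ContinuousRecording", fsHz = fs, channelLabels = "Cz",
             data = matrix(seq_len(n), 1),   # sample k holds the value k
             events = data.frame(sample_index = c(100L, 200L),
                                 label = c("cue_2_3_right", "go")))
  ep <- epochRecording(rec, "cue", windowMs = c(-100, 200))
  expect_identical(dim(signalData(ep)), c(1L, 1L, 30L))
  # window [-100, 200) at 100 Hz = samples 90..119 (0-based), values 91..120
  expect_equal(signalData(ep)[1, 1, ], 91:120)
  expect_equal(timesMs(ep), seq(-100, 190, by = 10))
  # conditions parsed from the cue label
  cond <- conditionTable(ep)
  expect_equal(cond$width, 2)
  expect_equal(cond$id, 3)
  expect_equal(cond$amplitude, 8)
  expect_identical(cond$hand, "right")
})

test_that("go- and lift-locked epochs inherit the preceding cue", {
  fs <- 100
  ev <- data.frame(sample_index = c(50L, 150L, 186L, 216L,
                                    450L, 550L, 590L, 620L),
                   label = rep(c("cue_1_4_left", "go", "lift", "tap"), 2))
  rec <- new("ContinuousRecording", fsHz = fs, channelLabels = "Cz",
             data = matrix(0, 1, 800), events = ev)
  ep <- epochRecording(rec, "lift", windowMs = c(-100, 100))
  expect_identical(dim(signalData(ep))[1], 2L)
  expect_identical(conditionTable(ep)$label,
                   rep("cue_1_4_left", 2))
  # a lift with no cue before it is an error
  ev2 <- data.frame(sample_index = c(10L, 50L), label = c("lift", "go"))
  rec2 <- new("ContinuousRecording", fsHz = fs, channelLabels = "Cz",
              data = matrix(0, 1, 100), events = ev2)
  expect_error(epochRecording(rec2, "lift"), "without a preceding cue")
  expect_error(epochRecording(rec2, "cue"), "no 'cue' events")
})

test_that("edge epochs are dropped with a message", {
  fs <- 100
  ev <- data.frame(sample_index = c(5L, 300L),
                   label = c("cue_2_3_right", "cue_2_2_left"))
  rec <- new("ContinuousRecording", fsHz = fs, channelLabels = "Cz",
             data = matrix(0, 1, 500), events = ev)
  expect_message(ep <- epochRecording(rec, "cue", windowMs = c(-100, 100)),
                 "dropped 1 epoch")
  expect_identical(dim(signalData(ep))[1], 1L)
  expect_identical(conditionTable(ep)$label, "cue_2_2_left")
})

test_that("condition maps must cover every cue label", {
  rec <- toyRecording(cueLabels = c("cue_2_3_right", "cue_2_3_right",
                                    "cue_1_2_left", "cue_1_2_left"))
  expect_error(
    epochRecording(rec, "cue", windowMs = c(0, 100),
                   conditionMap = c(cue_2_3_right = "easy")),
    "unmapped condition.*cue_1_2_left")
  ep <- epochRecording(rec, "cue", windowMs = c(0, 100),
                       conditionMap = c(cue_2_3_right = "hard",
                                        cue_1_2_left = "easy"))
  expect_identical(conditionTable(ep)$condition,
                   c("hard", "hard", "easy", "easy"))
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  set.seed(8)
  d <- array(rnorm(4 * 2 * 100, 10), c(4, 2, 100))
  ep <- toyEpochs(d, c("Cz", "Pz"), fs = 100, windowMs = c(-300, 700))
  out <- baselineCorrect(ep, c(-200, 0))
  bl <- timesMs(out) >= -200 & timesMs(out) < 0
  for (e in 1:4) for (ch in 1:2)
    expect_equal(mean(signalData(out)[e, ch, bl]), 0, tolerance = 1e-12)
  again <- baselineCorrect(out, c(-200, 0))
  expect_equal(signalData(again), signalData(out))
  expect_error(baselineCorrect(ep, c(-400, 0)), "within the epoch window")
  expect_error(baselineCorrect(ep, c(1, 2)), "no samples")
})

test_that("the rejection boundary at 100 microvolts is strict", {
  base <- array(0, c(3, 2, 50))
  base[1, 1, 1:2] <- c(0, 100)    # peak-to-peak exactly 100: kept
  base[2, 1, 1:2] <- c(0, 101)    # 101: rejected
  base[3, 2, 1:2] <- c(-50.5, 50)   # 100.5 on the second channel: rejected
  ep <- toyEpochs(base, c("Cz", "Pz"))
  out <- rejectArtifacts(ep, 100)
  expect_identical(rejected(out), c(FALSE, TRUE, TRUE))
  expect_match(rejectReason(out)[2], "Cz")
  expect_match(rejectReason(out)[3], "Pz")
})

test_that("EOG channels are excluded from rejection unless requested", {
  d <- array(0, c(1, 2, 50))
  d[1, 2, 1:2] <- c(0, 500)   # huge deflection on HEOG only
  ep <- toyEpochs(d, c("Cz", "HEOG"))
  expect_false(any(rejected(rejectArtifacts(ep, 100))))
  expect_true(any(rejected(rejectArtifacts(ep, 100,
                                           channels = c("Cz", "HEOG")))))
  expect_error(rejectArtifacts(ep, 100, channels = "Oz"), "unknown channel")
  expect_error(rejectArtifacts(ep, 0), "positive")
})

test_that("rejection flags accumulate monotonically", {
  d <- array(0, c(2, 1, 50))
  d[1, 1, 1:2] <- c(0, 60)
  ep <- toyEpochs(d, "Cz")
  once <- rejectArtifacts(ep, 50)     # epoch 1 rejected at 50 uV
  expect_identical(rejected(once), c(TRUE, FALSE))
  relaxed <- rejectArtifacts(once, 1000)   # raising the bar un-rejects nothing
  expect_identical(rejected(relaxed), c(TRUE, FALSE))
  expect_identical(rejectReason(relaxed)[1], rejectReason(once)[1])
})

test_that("averaging is the arithmetic mean over accepted epochs", {
  d <- array(0, c(4, 1, 10))
  d[1, , ] <- 1; d[2, , ] <- 3; d[3, , ] <- 10; d[4, , ] <- 100
  cond <- data.frame(label = c("a", "a", "a", "b"))
  ep <- toyEpochs(d, "Cz", conditions = cond)
  ep@rejected[3] <- TRUE
  erps <- averageEpochs(ep)
  expect_s4_class(erps, "ErpSet")
  tab <- conditionTable(erps)
  expect_equal(signalData(erps)[tab$label == "a", 1, ], rep(2, 10))
  expect_equal(tab$n[tab$label == "a"], 2L)
  # rejected epochs can be included explicitly for diagnostics
  diag <- averageEpochs(ep, excludeRejected = FALSE)
  expect_equal(signalData(diag)[1, 1, 1], mean(c(1, 3, 10)))
  # a condition with no accepted epochs errors by name
  ep@rejected[4] <- TRUE
  expect_error(averageEpochs(ep), "no accepted epochs for condition b")
  expect_error(averageEpochs(ep, by = "nope"), "unknown condition column")
})

test_that("epoch subsetting keeps data and metadata aligned", {
  set.seed(1)
  d <- array(rnorm(5 * 2 * 20), c(5, 2, 20))
  cond <- data.frame(label = paste0("c", 1:5))
  ep <- toyEpochs(d, c("Cz", "Pz"), conditions = cond)
  ep@rejected[2] <- TRUE
  sub <- ep[c(2, 4)]
  expect_identical(dim(signalData(sub))[1], 2L)
  expect_identical(conditionTable(sub)$label, c("c2", "c4"))
  expect_identical(rejected(sub), c(TRUE, FALSE))
  expect_equal(signalData(sub)[1, , ], d[2, , ])
  logi <- ep[conditionTable(ep)$label == "c5"]
  expect_identical(conditionTable(logi)$label, "c5")
})
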
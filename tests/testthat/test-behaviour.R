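test_that("extractRtMt converts marker intervals to milliseconds", {
  fs <- 500
  ev <- data.frame(
    sample_index = c(100L, 600L, 780L, 930L,    # rt 360 ms, mt 300 ms
                     2100L, 2600L, 2750L, 2900L),
    label = rep(c("cue_2_3_right", "go", "lift", "tap"), 2))
  got <- extractRtMt(ev, fs)
  expect_identical(nrow(got), 2L)
  expect_equal(got$rt, c(360, 300))
  expect_equal(got$mt, c(300, 300))
  expect_true(all(got$valid))
})

test_that("extractRtMt flags disordered or incomplete trials", {
  fs <- 500
  ev <- data.frame(
    sample_index = c(100L, 600L, 650L, 550L,    # tap before lift: disordered
                     2100L, 2600L,              # lift/tap missing
                     4100L, 4600L, 4800L, 4900L),
    label = c("cue_2_3_right", "go", "lift", "tap",
              "cue_2_3_left", "go",
              "cue_1_2_right", "go", "lift", "tap"))
  expect_message(got <- extractRtMt(ev[order(ev$sample_index), ], fs),
                 "2 trial")
  expect_equal(got$valid, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(got$rt[!got$valid])))
  expect_equal(got$rt[3], 400)
  # no-go cues yield no row
  ev2 <- data.frame(sample_index = c(10L, 510L), label = c("nogo", "go"))
  expect_identical(nrow(extractRtMt(ev2, fs)), 0L)
})

test_that("the trimming floor is exact at 100 ms", {
  tr <- makeTrials(rt = c(99, 100, 400, 410, 390, 405), mt = 400)
  out <- trimTrials(tr, floorMs = 100, sdMult = 1e6)
  expect_identical(nrow(out$removed), 1L)
  expect_equal(out$removed$rt, 99)
  expect_equal(out$removed$trimReason, "floor")
  expect_true(100 %in% out$kept$rt)   # exactly 100 ms is kept
  # the floor applies to MT as well
  tr2 <- makeTrials(rt = 400, mt = c(99, 100, 410, 400))
  out2 <- trimTrials(tr2, floorMs = 100, sdMult = 1e6)
  expect_equal(out2$removed$mt, 99)
})

test_that("the SD rule trims per condition using floor survivors", {
  rt <- c(400, 405, 395, 398, 402, 800)   # 800 is far outside 2 SD
  tr <- makeTrials(rt = rt, mt = 400)
  out <- trimTrials(tr)
  expect_equal(out$removed$rt, 800)
  expect_equal(out$removed$trimReason, "rt_sd")
  # a single pass: the rule is not re-applied after removal
  expect_identical(nrow(out$kept), 5L)
  # no-go rows pass through untouched
  nogo <- makeTrials(rt = NA, mt = NA)
  nogo$isNogo <- TRUE; nogo$cueType <- "nogo"
  both <- rbind(tr, nogo)
  out2 <- trimTrials(both)
  expect_true(any(out2$kept$isNogo))
  expect_error(trimTrials(tr, floorMs = -1), "non-negative")
  expect_error(trimTrials(tr, sdMult = 0), "positive")
})

test_that("cell summaries exclude incorrect responses from the means", {
  tr <- makeTrials(rt = c(300, 310, 320, 900), mt = c(400, 410, 420, 900))
  tr$miss[4] <- TRUE
  cs <- cellSummaries(tr)
  expect_identical(cs$n, 4L)
  expect_equal(cs$meanRt, mean(c(300, 310, 320)))
  expect_equal(cs$meanMt, mean(c(400, 410, 420)))
  expect_equal(cs$missRate, 0.25)
})

test_that("fittsRegression recovers an exact linear law on cell means", {
  d <- buildDesign()
  cells <- designCells(d)
  tr <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    makeTrials(rt = c(350, 350), mt = 211 + 68 * cells$id[i],
               width = cells$width[i], id = cells$id[i])))
  fit <- fittsRegression(tr, "id")
  expect_equal(fit@slope, 68, tolerance = 1e-12)
  expect_equal(fit@intercept, 211, tolerance = 1e-12)
  expect_equal(fit@r2, 1)
  expect_identical(fit@n, 9L)
  # an amplitude-linear law is recovered by the amplitude regression
  tr2 <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    makeTrials(rt = c(350, 350), mt = 360 + 5 * cells$amplitude[i],
               width = cells$width[i], id = cells$id[i])))
  fit2 <- fittsRegression(tr2, "amplitude")
  expect_equal(fit2@slope, 5, tolerance = 1e-12)
  expect_equal(fit2@intercept, 360, tolerance = 1e-12)
})

test_that("errorTable reports per-cell miss and per-cue wrong-target rates", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 4L, seed = 9L)
  tr <- simulateBehaviour(d, cfg)
  et <- errorTable(tr)
  expect_identical(nrow(et$missByCell), 9L)
  expect_identical(nrow(et$wrongByCue), 3L)
  expect_equal(sum(et$missByCell$n), sum(!tr$isNogo))
  act <- tr[!tr$isNogo, ]
  expect_equal(weighted.mean(et$missByCell$missRate, et$missByCell$n),
               mean(act$miss))
})

test_that("subjectHandMeans feeds the hand t-test", {
  trL <- makeTrials(rt = c(400, 410), mt = 300, hand = "left")
  trR <- makeTrials(rt = c(380, 390), mt = 300, hand = "right")
  hm <- subjectHandMeans(rbind(trL, trR))
  expect_equal(hm$left, 405)
  expect_equal(hm$right, 385)
})
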
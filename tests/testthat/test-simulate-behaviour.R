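test_that("behaviour simulation is deterministic and subject-specific", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 2L, seed = 5L)
  a <- simulateBehaviour(d, cfg, 2L)
  b <- simulateBehaviour(d, cfg, 2L)
  expect_identical(a, b)
  s1 <- a[a$subject == 1, ]
  s2 <- a[a$subject == 2, ]
  expect_false(identical(s1$rt, s2$rt))
  # subject streams are independent of how many subjects run alongside
  solo <- simulateBehaviour(d, cfg, 2L, subjects = 2L)
  expect_identical(solo$rt, s2$rt)
})

test_that("the trial plan respects the block structure", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 1L, seed = 3L)
  tr <- simulateBehaviour(d, cfg)
  expect_identical(nrow(tr), 12L * 63L)
  # every cue type occurs equally often within every block
  for (b in unique(tr$block))
    expect_true(all(table(tr$cueType[tr$block == b]) == 9L))
  # constant width within a block, each width in 4 of the 12 blocks
  byBlock <- tapply(tr$width[!tr$isNogo], tr$block[!tr$isNogo],
                    function(w) length(unique(w)))
  expect_true(all(byBlock == 1L))
  expect_equal(as.integer(table(tapply(tr$width[!tr$isNogo],
                                       tr$block[!tr$isNogo], unique))),
               c(4L, 4L, 4L))
  # no-go trials carry no response
  expect_true(all(is.na(tr$rt[tr$isNogo])))
  expect_true(all(is.na(tr$mt[tr$isNogo])))
  expect_true(all(is.finite(tr$rt[!tr$isNogo])))
  # the stored ID satisfies the Fitts identity
  act <- tr[!tr$isNogo, ]
  expect_equal(computeID(act$amplitude, act$width), act$id)
})

test_that("event times are ordered and inside the trial period", {
  d <- buildDesign()
  tr <- simulateBehaviour(d, generatorConfig(nSubjects = 1L, seed = 2L), 3L)
  act <- tr[!tr$isNogo, ]
  expect_true(all(act$cueOnsetMs < act$goOnsetMs))
  expect_true(all(act$goOnsetMs < act$liftMs))
  expect_true(all(act$liftMs < act$tapMs))
  trialStart <- (act$block - 1) * 63 * 4000 + (act$trialInBlock - 1) * 4000
  expect_true(all(act$tapMs < trialStart + 4000))
})

test_that("noise-free behaviour reproduces the generating laws exactly", {
  d <- buildDesign()
  cfg <- noiselessConfig(nSubjects = 2L, seed = 1L)
  tr <- simulateBehaviour(d, cfg)
  act <- tr[!tr$isNogo, ]
  expect_equal(act$mt, 211 + 68 * act$id)
  # right hand faster by the full 15 ms offset (split +/- 7.5 around 360)
  expect_equal(unique(act$rt[act$hand == "right"]), 360 - 7.5)
  expect_equal(unique(act$rt[act$hand == "left"]), 360 + 7.5)
  expect_false(any(act$miss))
  expect_false(any(act$wrongTarget))
})

test_that("miss rates follow the configured per-cell probabilities", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 8L, seed = 4L)
  tr <- simulateBehaviour(d, cfg)
  act <- tr[!tr$isNogo, ]
  # hardest cell (width 1) should miss far more often than easiest (width 4)
  expect_gt(mean(act$miss[act$width == 1]), mean(act$miss[act$width == 4]))
  # overall rate is in the ballpark of the configured 0.1-2% cells
  expect_lt(mean(act$miss), 0.05)
  expect_gt(mean(act$miss), 0.001)
  # a missed trial is never also a wrong-target trial
  expect_false(any(act$miss & act$wrongTarget))
})

test_that("blocksPerSubject is bounded by the design", {
  d <- buildDesign()
  cfg <- generatorConfig(nSubjects = 1L)
  expect_error(simulateBehaviour(d, cfg, 0L), "between 1 and")
  expect_error(simulateBehaviour(d, cfg, 13L), "between 1 and")
})
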
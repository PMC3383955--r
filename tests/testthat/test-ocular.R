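test_that("fitOcularModel recovers known propagation coefficients", {
  ep <- makeOcularEpochs()
  om <- fitOcularModel(ep)
  expect_identical(om@eogChannels, c("VEOG", "HEOG"))
  expect_equal(om@coefficients["VEOG", "Cz"], 0.25, tolerance = 0.05)
  expect_equal(om@coefficients["VEOG", "Pz"], 0.08, tolerance = 0.05)
  expect_equal(om@coefficients["HEOG", "Cz"], 0.04, tolerance = 0.05)
})

test_that("fitOcularModel matches a sequential lm oracle exactly", {
  ep <- makeOcularEpochs(nEp = 12)
  om <- fitOcularModel(ep)
  # oracle: subtract condition averages, then per-channel simple regression,
  # horizontal EOG fitted on vertical-corrected residuals
  d <- signalData(ep)
  cond <- conditionTable(ep)$label
  res <- d
  for (g in unique(cond)) {
    idx <- which(cond == g)
    avg <- colMeans(d[idx, , , drop = FALSE])
    for (i in idx) res[i, , ] <- d[i, , ] - avg
  }
  v <- as.vector(res[, 3, ]); h <- as.vector(res[, 4, ])
  for (ch in 1:2) {
    y <- as.vector(res[, ch, ])
    bV <- unname(coef(lm(y ~ v))[2])
    bH <- unname(coef(lm(I(y - bV * v) ~ h))[2])
    expect_equal(om@coefficients["VEOG", ch], bV, tolerance = 1e-6)
    expect_equal(om@coefficients["HEOG", ch], bH, tolerance = 1e-6)
  }
})

test_that("applying a correction removes the propagated artifact", {
  ep <- makeOcularEpochs(nEp = 40)
  om <- fitOcularModel(ep)
  corrected <- applyOcularModel(ep, om)
  # EOG channels are passed through untouched
  expect_equal(signalData(corrected)[, 3:4, ], signalData(ep)[, 3:4, ])
  # residual blink propagation on Cz is much smaller after correction:
  # correlate single-trial Cz with VEOG after condition-average subtraction
  resCor <- function(e) {
    d <- signalData(e)
    cond <- conditionTable(e)$label
    res <- d
    for (g in unique(cond)) {
      idx <- which(cond == g)
      avg <- colMeans(d[idx, , , drop = FALSE])
      for (i in idx) res[i, , ] <- d[i, , ] - avg
    }
    abs(cor(as.vector(res[, 1, ]), as.vector(res[, 3, ])))
  }
  expect_lt(resCor(corrected), 0.05)
  expect_gt(resCor(ep), 0.5)
})

test_that("an exact model removes the artifact exactly", {
  labels <- c("Cz", "VEOG", "HEOG")
  om <- new("OcularModel", eogChannels = "VEOG", eegChannels = "Cz",
            coefficients = matrix(0.2, 1, 1,
                                  dimnames = list("VEOG", "Cz")))
  set.seed(5)
  veog <- rnorm(50)
  brain <- sin(seq_len(50) / 5)
  rec <- new("ContinuousRecording", fsHz = 100, channelLabels = labels,
             data = rbind(Cz = brain + 0.2 * veog, VEOG = veog,
                          HEOG = rnorm(50)),
             events = data.frame())
  out <- applyOcularModel(rec, om)
  expect_equal(signalData(out)["Cz", ], brain, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ocular fitting validates its inputs", {
  ep <- makeOcularEpochs(nEp = 8)
  expect_error(fitOcularModel(ep, conditionColumn = "nope"), "not found")
  expect_error(fitOcularModel(ep, eogChannels = "EOGX"),
               "not an available EOG channel")
  # restricting to VEOG yields a vertical-only model
  om <- fitOcularModel(ep, eogChannels = "VEOG")
  expect_identical(om@eogChannels, "VEOG")
  expect_identical(nrow(om@coefficients), 1L)
  # fewer than 2 epochs per condition
  one <- ep[c(1, 2, 3)]
  expect_error(fitOcularModel(one), ">= 2 epochs")
  # flat EOG
  d <- signalData(ep)
  d[, 3, ] <- 0
  flat <- toyEpochs(d, c("Cz", "Pz", "VEOG", "HEOG"),
                    conditions = conditionTable(ep))
  expect_error(fitOcularModel(flat), "flat EOG")
  # no EOG channels at all
  noEog <- toyEpochs(d[, 1:2, , drop = FALSE], c("Cz", "Pz"),
                     conditions = conditionTable(ep))
  expect_error(fitOcularModel(noEog), "no EOG")
  # applying to data missing a channel
  om2 <- fitOcularModel(ep)
  rec <- new("ContinuousRecording", fsHz = 100, channelLabels = c("Cz", "VEOG"),
             data = matrix(0, 2, 10), events = data.frame())
  expect_error(applyOcularModel(rec, om2), "not present")
})
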
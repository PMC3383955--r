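test_that("roiWindowMean pools electrodes and the half-open window", {
  labels <- c(posteriorRoi(), "Cz")
  nT <- 200   # 0..995 ms at 200 Hz
  d <- array(0, c(2, 7, nT))
  t <- (0:(nT - 1)) * 5
  win <- t >= 310 & t < 370
  d[1, 1:6, win] <- 2.5           # constant in the window on the ROI
  d[1, 7, ] <- 99                 # Cz is not part of the ROI
  d[2, 1:6, win] <- rep(seq(-1, 1, length.out = sum(win)), each = 6)
  cond <- data.frame(label = c("cue_2_3_right", "cue_2_2_left"))
  erps <- toyErps(d, labels, cond, fs = 200)
  got <- roiWindowMean(erps)
  expect_equal(got$value[1], 2.5)
  expect_equal(got$value[2], 0)
  expect_identical(got$measure, rep("n2p3b", 2))
  # a sample at exactly 370 ms is excluded
  d2 <- array(0, c(1, 7, nT))
  d2[1, 1:6, t == 370] <- 1000
  erps2 <- toyErps(d2, labels, cond[1, , drop = FALSE], fs = 200)
  expect_equal(roiWindowMean(erps2)$value, 0)
  expect_error(roiWindowMean(erps, channels = "Oz"), "missing electrode")
  expect_error(roiWindowMean(erps, windowMs = c(2000, 2100)), "no samples")
})

test_that("motorCNV subtracts the no-go average", {
  labels <- c("Cz", "FCz", "CPz", "C1", "C2", "Pz")
  nT <- 240   # 0..1195 ms at 200 Hz
  t <- (0:(nT - 1)) * 5
  win <- t >= 800 & t < 1000
  d <- array(0, c(3, 6, nT))
  d[1, 1:5, win] <- -6    # action condition A
  d[2, 1:5, win] <- -3    # action condition B
  d[3, 1:5, win] <- -2    # no-go (anticipatory part)
  cond <- data.frame(label = c("A", "B", "nogo"), width = c(1, 2, NA),
                     id = c(2, 3, NA))
  erps <- toyErps(d, labels, cond, fs = 200)
  got <- motorCNV(erps)
  expect_equal(got$value, c(-4, -1))
  expect_identical(got$measure, rep("motor_cnv", 2))
  expect_identical(got$label, c("A", "B"))
  expect_error(motorCNV(erps, nogoLabel = "rest"), "absent")
})

test_that("the LRP cancels symmetric activity and flips with hand", {
  labels <- c("C1", "C2", "C3", "C4", "Cz")
  nT <- 100
  t <- seq(-400, 95, by = 5)
  sym <- matrix(rep(sin(seq_len(nT) / 7), 5), 5, nT, byrow = TRUE,
                dimnames = list(labels, NULL))
  contra <- matrix(0, 5, nT)
  contra[c(1, 3), t >= -200 & t < 0] <- -2   # C1/C3 active for right hand
  left <- sym + contra[c(2, 1, 4, 3, 5), ]   # mirrored for the left hand
  right <- sym + contra
  rownames(left) <- rownames(right) <- labels
  got <- lrpAmplitude(left, right, timesMs = t)
  expect_equal(got$value, -2)
  # purely symmetric activity cancels exactly
  none <- lrpAmplitude(sym, sym, timesMs = t)
  expect_equal(none$value, 0)
  # swapping the hands flips the sign exactly
  flipped <- lrpAmplitude(right, left, timesMs = t)
  expect_equal(flipped$value, 2)
  expect_error(lrpAmplitude(left, right), "timesMs required")
  expect_error(lrpAmplitude(left[1:2, ], right[1:2, ], timesMs = t),
               "missing electrode")
})

test_that("ErpSet-based LRP matches conditions across hands", {
  labels <- c("C1", "C2", "C3", "C4")
  nT <- 100
  t <- seq(-400, 95, by = 5)
  mk <- function(vals, hand) {
    d <- array(0, c(length(vals), 4, nT))
    for (i in seq_along(vals)) {
      contra <- if (hand == "right") c(1, 3) else c(2, 4)
      d[i, contra, t >= -200 & t < 0] <- vals[i]
    }
    toyErps(d, labels,
            data.frame(width = c(1, 2)[seq_along(vals)],
                       id = 3, hand = hand, n = 10L),
            fs = 200, t0Ms = -400, lockEvent = "lift")
  }
  lft <- mk(c(-1, -3), "left")
  rgt <- mk(c(-1, -3), "right")
  got <- lrpAmplitude(lft, rgt)
  expect_equal(got$value, c(-1, -3))
  expect_equal(got$width, c(1, 2))
  # a left-hand condition without a right-hand partner is an error
  expect_error(lrpAmplitude(lft, rgt[1]), "missing right-hand average")
})

test_that("lateralizedHEOG sign-aligns target sides", {
  labels <- c("Cz", "HEOG")
  fs <- 200
  nT <- 300   # cue-locked 0..1495 ms
  t <- (0:(nT - 1)) * 5
  win <- t >= 1250 & t < 1450   # 250-450 ms after the 1000 ms foreperiod
  mk <- function(heogVal, hand, width = 2, id = 3) {
    d <- array(0, c(1, 2, nT))
    d[1, 2, win] <- heogVal
    list(d = d, cond = data.frame(label = "x", width = width, id = id,
                                  hand = hand, isNogo = FALSE))
  }
  a <- mk(-140, "right"); b <- mk(140, "left")
  d <- array(0, c(2, 2, nT)); d[1, , ] <- a$d; d[2, , ] <- b$d
  ep <- toyEpochs(d, labels, fs = fs, windowMs = c(0, 1500),
                  conditions = rbind(a$cond, b$cond))
  got <- lateralizedHEOG(ep)
  # both sides align to -140 after the left-side flip
  expect_equal(got$value, -140)
  expect_identical(got$measure, "lheog")
  expect_equal(got$n, 2L)
  # a single side still works but warns
  expect_warning(one <- lateralizedHEOG(ep[1]), "one side")
  expect_equal(one$value, -140)
  # rejected epochs are excluded
  ep@rejected[1] <- TRUE
  expect_warning(got2 <- lateralizedHEOG(ep), "one side")
  expect_equal(got2$value, -140)
})

test_that("erpRegression derives amplitude and validates predictors", {
  m <- data.frame(width = c(1, 1, 1, 2, 2, 2), id = rep(c(2, 3, 4), 2))
  m$amplitude <- m$width * 2^m$id / 2
  m$value <- -133 - 3.8 * m$amplitude
  fit <- erpRegression(m[, c("width", "id", "value")], "amplitude")
  expect_equal(fit@slope, -3.8, tolerance = 1e-12)
  expect_equal(fit@intercept, -133, tolerance = 1e-12)
  expect_equal(fit@r2, 1)
  fit2 <- erpRegression(data.frame(id = c(2, 3, 4),
                                   value = -2.3 + 1.6 * c(2, 3, 4)), "id")
  expect_equal(fit2@slope, 1.6, tolerance = 1e-12)
  expect_error(erpRegression(data.frame(value = 1:3), "id"), "not found")
  expect_error(erpRegression(data.frame(id = c(1, 1, 2), value = 1:3), "id"),
               ">= 3 distinct")
})
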
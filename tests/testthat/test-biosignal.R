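test_that("rectification is the absolute value and idempotent", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(rep(0, 5)), rep(0, 5))
  x <- stats::rnorm(100)
  expect_identical(rectify(rectify(x)), rectify(x))
  expect_error(rectify(c(1, NA)), "finite")
})

test_that("the moving average shrinks at the edges and conserves mass", {
  expect_equal(movingAverage(rep(3, 7), 3, 1), rep(3, 7))
  expect_equal(movingAverage(c(0, 0, 4, 0, 0), 3, 1),
               c(0, 4 / 3, 4 / 3, 4 / 3, 0))
  # impulse energy: interior-supported impulse keeps its sum
  x <- numeric(21); x[11] <- 5
  expect_equal(sum(movingAverage(x, 5, 1)), 5)
  # oracle: centered convolution on the interior
  y <- stats::rnorm(50)
  sm <- movingAverage(y, 5, 1)
  conv <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  expect_equal(sm[3:48], as.numeric(conv[3:48]))
  expect_error(movingAverage(y, 0.1, 1), "window")
})

test_that("subject-max and unit-interval normalization scale as specified", {
  nrm <- makeNormalizer(emgMax = 10)
  expect_equal(subjectMaxNormalize(c(5, 10), nrm, "emg"), c(0.5, 1))
  expect_equal(subjectMaxNormalize(rep(10, 4), nrm, "emg"), rep(1, 4))
  nrm2 <- makeNormalizer(emgMax = 20)
  expect_false(identical(subjectMaxNormalize(5, nrm, "emg"),
                         subjectMaxNormalize(5, nrm2, "emg")))
  expect_error(makeNormalizer(emgMax = 0), "positive")

  expect_equal(unitIntervalNormalize(c(2, 4)), c(0.5, 1))
  expect_equal(unitIntervalNormalize(c(1, 1, 1)), c(1, 1, 1))
  for (i in 1:5) {
    v <- stats::runif(10)
    expect_equal(max(unitIntervalNormalize(v)), 1)
  }
  expect_error(unitIntervalNormalize(c(-1, 0)), "degenerate")
})

test_that("resampling interpolates linearly onto the 25 Hz grid", {
  expect_equal(resampleSignal(rep(5, 160), 100), rep(5, 40))
  expect_length(resampleSignal(stats::runif(3200), 2000), 40L)
  # a linear ramp is reproduced exactly at the target times
  t100 <- (0:159) / 100
  ramp <- 2 + 3 * t100
  out <- resampleSignal(ramp, 100)
  expect_equal(out, 2 + 3 * (0:39) / 25, tolerance = 1e-12)
  expect_error(resampleSignal(1:10, 10), "upsampling")
})

test_that("pressure region averages match the brute-force assignment", {
  layout <- defaultPressureLayout()
  expect_equal(unname(pressureRegionAverage(rep(2, 64))), rep(2, 6))
  frame <- numeric(64)
  frame[layout == 1L] <- 3   # left heel only
  out <- pressureRegionAverage(frame)
  expect_equal(unname(out["L1"]), 3)
  expect_equal(unname(out[c("L2", "L3", "R1", "R2", "R3")]), rep(0, 5))
  rnd <- stats::runif(64)
  out <- pressureRegionAverage(rnd)
  for (r in 1:6)
    expect_equal(unname(out[r]), mean(rnd[layout == r]))
  expect_error(pressureRegionAverage(rnd, layout = rep(1L, 64)), "layout")
})

test_that("offset removal centers stationary acceleration at zero", {
  off <- c(0.3, -0.2, 1.0)
  x <- matrix(stats::rnorm(300 * 3, sd = 0.02), 300, 3)
  x <- sweep(x, 2, off, "+")
  y <- accRemoveOffset(x, off)
  expect_true(all(abs(colMeans(y)) < 0.02 / sqrt(300) * 5))
  expect_equal(accRemoveOffset(x, c(0, 0, 0)), x)
  expect_error(accRemoveOffset(x, c(1, 2)), "offsets")
})

test_that("feature dimensions follow n_channels x round(25 W)", {
  nrm <- makeNormalizer()
  emgClip <- makeClip(3200, 8, 2000)
  expect_length(buildBiosignalFeature(emgClip, "emg", nrm), 320L)
  pressClip <- makeClip(160, 64, 100)
  expect_length(buildBiosignalFeature(pressClip, "pressure", nrm), 240L)
  accClip <- makeClip(160, 3, 100)
  expect_length(buildBiosignalFeature(accClip, "acc", nrm), 120L)
})

test_that("feature values are max-normalized before resampling", {
  nrm <- makeNormalizer()
  for (sensor in c("emg", "pressure", "acc")) {
    clip <- makeClip(c(emg = 3200, pressure = 160, acc = 160)[[sensor]],
                     c(emg = 8, pressure = 64, acc = 3)[[sensor]],
                     c(emg = 2000, pressure = 100, acc = 100)[[sensor]])
    f <- buildBiosignalFeature(clip, sensor, nrm)
    expect_lte(max(f), 1)
    expect_gt(max(f), 0.9)   # resampling may shave the peak only slightly
  }
})

test_that("the EMG chain matches an independently coded reference", {
  # independent oracle: plain-loop implementation of the same chain
  clip <- makeClip(400, 8, 250)
  nrm <- makeNormalizer(emgMax = 0.7)
  got <- buildBiosignalFeature(clip, "emg", nrm)

  k <- round(0.1 * 250)
  sm <- sapply(1:8, function(ch) {
    x <- abs(clip[, ch])
    sapply(seq_along(x), function(i) {
      lo <- (k - 1) %/% 2
      mean(x[max(1, i - lo):min(length(x), i + (k - 1 - lo))])
    })
  })
  sm <- sm / 0.7
  sm <- sm / max(sm)
  tIn <- (0:399) / 250
  m <- round(400 / 250 * 25)
  tOut <- (0:(m - 1)) / 25
  want <- as.numeric(sapply(1:8, function(ch)
    stats::approx(tIn, sm[, ch], xout = tOut)$y))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("feature vectors are invariant to subject-level amplitude scaling", {
  ch <- generateCohort(tinyConfig(seed = 14))
  rec <- ch$recordings[[1]]
  seg <- ch$segments[ch$segments$subject == subjectId(rec), ][2, ]
  f1 <- buildBiosignalFeature(extractWindow(rec, seg, "emg"), "emg",
                              computeNormalizer(rec))
  scaled <- rec
  scaled@emg <- rec@emg * 3.7
  f2 <- buildBiosignalFeature(extractWindow(scaled, seg, "emg"), "emg",
                              computeNormalizer(scaled))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("normalizer offsets recover the true accelerometer offset", {
  ch <- generateCohort(tinyConfig(seed = 15))
  nrm <- computeNormalizer(ch$recordings[[1]])
  # lead-in mean should sit near the nominal offset (0.3, -0.2, 1.0)
  expect_equal(nrm@accOffset, c(0.3, -0.2, 1.0), tolerance = 0.15)
  expect_gt(nrm@emgMax, 0)
  expect_gt(nrm@pressureMax, 0)
})
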
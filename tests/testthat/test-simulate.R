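test_that("equal seeds give identical cohorts, different seeds differ", {
  c1 <- generateCohort(tinyConfig(seed = 5))
  c2 <- generateCohort(tinyConfig(seed = 5))
  expect_identical(c1$segments, c2$segments)
  expect_identical(emgSignal(c1$recordings[[1]]),
                   emgSignal(c2$recordings[[1]]))
  expect_identical(accSignal(c1$recordings[[2]]),
                   accSignal(c2$recordings[[2]]))
  c3 <- generateCohort(tinyConfig(seed = 6))
  expect_false(identical(c1$segments, c3$segments))
})

test_that("lazy video rendering is deterministic and order-independent", {
  c1 <- generateCohort(tinyConfig(seed = 5))
  c2 <- generateCohort(tinyConfig(seed = 5))
  f1 <- getFrames(videoStream(c1$recordings[[1]]), c(7, 150, 2))
  invisible(getFrames(videoStream(c2$recordings[[2]]), 1))
  f2 <- getFrames(videoStream(c2$recordings[[1]]), c(7, 150, 2))
  expect_identical(f1, f2)
})

test_that("per-subject segment counts respect the repetition range", {
  cfg <- cohortConfig(nSubjects = 2, repsRange = c(19, 46), seed = 3,
                      videoSize = c(48, 48))
  ch <- generateCohort(cfg)
  for (s in unique(ch$segments$subject)) {
    n <- sum(ch$segments$subject == s)
    expect_gte(n, 12 * 19)
    expect_lte(n, 12 * 46)
    perAct <- table(ch$segments$activity[ch$segments$subject == s])
    expect_length(perAct, 12L)
    expect_true(all(perAct >= 19 & perAct <= 46))
  }
})

test_that("segments lie within the recorded span of all four sensors", {
  ch <- generateCohort(tinyConfig(seed = 8))
  for (i in seq_along(ch$recordings)) {
    rec <- ch$recordings[[i]]
    segs <- ch$segments[ch$segments$subject == subjectId(rec), ]
    rates <- samplingRates(rec)
    spans <- c(emg = nrow(emgSignal(rec)) / rates[["emg"]],
               pressure = nrow(pressureSignal(rec)) / rates[["pressure"]],
               acc = nrow(accSignal(rec)) / rates[["acc"]],
               video = nFrames(videoStream(rec)) / rates[["video"]])
    expect_true(all(segs$t_start > 0))
    expect_true(all(segs$t_end < min(spans)))
    # non-overlapping within a subject
    segs <- segs[order(segs$t_start), ]
    expect_true(all(segs$t_start[-1] >= segs$t_end[-nrow(segs)]))
  }
})

test_that("degenerate noise gives identical windows across repetitions", {
  ch <- generateCohort(noiselessConfig())
  for (sensor in c("emg", "pressure", "acc")) {
    segs <- ch$segments[ch$segments$activity == "4a", ]
    w1 <- extractWindow(ch$recordings[[1]], segs[1, ], sensor)
    w2 <- extractWindow(ch$recordings[[1]], segs[2, ], sensor)
    expect_equal(unclass(w1), unclass(w2), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("the stationary lead-in is quiet and at least 10 s long", {
  ch <- generateCohort(tinyConfig(seed = 4))
  rec <- ch$recordings[[1]]
  expect_gte(rec@leadIn, 10)
  nLead <- 10 * samplingRates(rec)[["acc"]]
  lead <- accSignal(rec)[seq_len(nLead), ]
  # stationary: the lead-in fluctuates around a constant offset
  expect_lt(max(apply(lead, 2, stats::sd)), 5 * 0.03)
  frames <- getFrames(videoStream(rec), c(1, 100))
  expect_lt(max(abs(frames[, , 1] - frames[, , 2])), 0.1)
})

test_that("rendered clips have the requested frame count and structure", {
  cfg <- tinyConfig()
  clip <- renderSilhouetteVideo("1a", 1.6, cfg)
  expect_equal(dim(clip), c(48, 48, 40))
  expect_true(all(clip >= 0 & clip <= 1))
  stand <- renderSilhouetteVideo("stand", 0.4, cfg)
  for (k in 2:dim(stand)[3])
    expect_identical(stand[, , k], stand[, , 1])
  # moving clip: frames are textured and non-constant
  expect_gt(stats::sd(clip[, , 20]), 0.01)
  expect_gt(max(abs(clip[, , 21] - clip[, , 20])), 0.01)
  expect_error(renderSilhouetteVideo("1a", 0, cfg), "positive")
})

test_that("translation clips store their ground-truth displacement", {
  clip <- renderTranslationClip(90, speed = 1.5, nFrames = 4,
                                width = 48, height = 40)
  expect_equal(dim(clip), c(40, 48, 4))
  gt <- attr(clip, "displacement")
  expect_equal(unname(gt), c(0, -1.5), tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(repsRange = c(0, 5)), "repsRange")
  expect_error(cohortConfig(emgRate = -1), "rates")
  expect_error(cohortConfig(leadIn = 5), "lead")
})
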
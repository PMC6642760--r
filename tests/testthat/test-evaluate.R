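# A small hand-checkable prediction set used in several tests: two
# subjects, three activities, known correct counts.
toyPredictions <- function() {
  mk <- function(subject, activity, n, correct, wrong = "2a") {
    data.frame(subject = subject, activity = activity,
               pred = c(rep(activity, correct),
                        rep(if (activity == wrong) "1a" else wrong,
                            n - correct)))
  }
  rbind(mk("S1", "1a", 4, 3), mk("S1", "1b", 2, 2), mk("S1", "2a", 3, 1),
        mk("S2", "1a", 2, 1), mk("S2", "1b", 3, 3), mk("S2", "2a", 2, 2))
}

test_that("recognition rate is a plain percentage with guarded bounds", {
  expect_equal(recognitionRate(49, 50), 98)
  expect_equal(recognitionRate(0, 7), 0)
  expect_equal(recognitionRate(7, 7), 100)
  expect_error(recognitionRate(1, 0), "positive")
  expect_error(recognitionRate(8, 7), "correct")
})

test_that("weightedSD reduces to the sample SD under equal weights", {
  expect_equal(weightedSD(c(0, 100), c(1, 1), center = 50),
               sqrt(5000), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    x <- stats::runif(8, 0, 100)
    expect_equal(weightedSD(x, rep(3, 8), center = mean(x)),
                 stats::sd(x), tolerance = 1e-9)
  }
  # scale invariance in the weights
  x <- c(10, 60, 90); w <- c(2, 5, 1)
  expect_equal(weightedSD(x, w, 50), weightedSD(x, 2 * w, 50),
               tolerance = 1e-12)
  expect_equal(weightedSD(rep(80, 5), stats::runif(5, 1, 9), 80), 0)
  expect_error(weightedSD(1, 1, 1), "2 groups")
  expect_error(weightedSD(c(1, 2), c(1, 0), 1), "positive")
})

test_that("the confusion matrix is column-normalized with R on the diagonal", {
  pred <- toyPredictions()
  cm <- buildConfusion(pred$activity, pred$pred)
  expect_equal(unname(colSums(confusionPercent(cm))), rep(100, 3))
  rep_ <- buildReport(pred)
  expect_equal(unname(diag(confusionPercent(cm))),
               activityStats(rep_)$R, tolerance = 1e-12)
  # printed-count toy: column A = (66.67, 33.33, 0)
  cm3 <- buildConfusion(c("A", "A", "A", "B", "C"),
                        c("A", "A", "B", "B", "C"),
                        labels = c("A", "B", "C"))
  expect_equal(unname(confusionPercent(cm3)[, "A"]),
               c(200 / 3, 100 / 3, 0), tolerance = 1e-12)
  expect_error(buildConfusion(c("A", "A"), c("A", "B"),
                              labels = c("A", "B")), "zero repetitions")
})

test_that("perfect predictions give R = 100 and U = 0 everywhere", {
  pred <- data.frame(subject = rep(c("S1", "S2"), each = 6),
                     activity = rep(c("1a", "1b", "2a"), 4))
  pred$pred <- pred$activity
  rep_ <- buildReport(pred)
  expect_true(all(activityStats(rep_)$R == 100))
  expect_true(all(activityStats(rep_)$U == 0))
  expect_true(all(subjectStats(rep_)$R == 100))
  expect_equal(unname(overallStats(rep_)[c("R_all", "U_all", "U_act_all")]),
               c(100, 0, 0))
})

test_that("the overall rate is the count-weighted mean of activity rates", {
  pred <- toyPredictions()
  rep_ <- buildReport(pred)
  pa <- activityStats(rep_)
  expect_equal(unname(overallStats(rep_)["R_all"]),
               sum(pa$R * pa$W) / sum(pa$W), tolerance = 1e-12)
  expect_equal(unname(overallStats(rep_)["R_all"]),
               100 * sum(pa$P) / sum(pa$W), tolerance = 1e-12)
})

test_that("absent subjects or activities are reported as missing rows", {
  pred <- toyPredictions()
  rep_ <- buildReport(pred, subjects = c("S1", "S2", "S3"),
                      activities = c("1a", "1b", "2a", "2b"))
  pa <- activityStats(rep_)
  expect_true(is.na(pa$R[pa$activity == "2b"]))
  ps <- subjectStats(rep_)
  expect_true(is.na(ps$R[ps$subject == "S3"]))
  expect_equal(ps$W[ps$subject == "S3"], 0L)
})

test_that("recognition and dispersion are anti-correlated across activities", {
  # heterogeneous subjects: some sloppy performers depress per-activity
  # rates unevenly, which the dispersion statistic should pick up
  set.seed(43)
  subjects <- paste0("S", 1:8)
  sloppy <- c(0.05, 0.1, 0.15, 0.2, 0.45, 0.5, 0.2, 0.1)
  pred <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    do.call(rbind, lapply(activityLevels(), function(a) {
      n <- 25
      errRate <- sloppy[i] * stats::runif(1, 0, 2)
      wrong <- sample(setdiff(activityLevels(), a), n, replace = TRUE)
      take <- stats::runif(n) < errRate
      data.frame(subject = subjects[i], activity = a,
                 pred = ifelse(take, wrong, a))
    }))
  }))
  rep_ <- buildReport(pred)
  pa <- activityStats(rep_)
  expect_lt(stats::cor(pa$R, pa$U, method = "spearman"), 0)
})

test_that("report tables are written in the published shapes", {
  pred <- toyPredictions()
  reports <- list(emg = buildReport(pred, sensor = "emg"),
                  acc = buildReport(pred, sensor = "acc"))
  confusions <- list(emg = buildConfusion(pred$activity, pred$pred))
  dir <- withr::local_tempdir()
  paths <- writeReportTables(reports, confusions, dir)
  t1 <- utils::read.csv(file.path(dir, "table1.csv"), check.names = FALSE)
  expect_equal(nrow(t1), 4L)             # R and U rows per sensor
  expect_equal(t1$sensor, c("B", "B", "E", "E"))
  expect_true(all(c("1a", "1b", "2a", "All") %in% names(t1)))
  t6 <- utils::read.csv(file.path(dir, "table6.csv"), check.names = FALSE)
  expect_true(all(c("S1", "S2", "All") %in% names(t6)))
  cm <- utils::read.csv(file.path(dir, "confusion_B.csv"), row.names = 1)
  expect_equal(dim(cm), c(3L, 3L))
})
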
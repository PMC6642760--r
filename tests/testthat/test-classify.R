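test_that("the Manhattan distance satisfies its metric properties", {
  expect_equal(manhattanDist(c(0, 0), c(1, 2)), 3)
  x <- stats::rnorm(20)
  expect_equal(manhattanDist(x, x), 0)
  set.seed(31)
  for (i in 1:20) {
    a <- stats::rnorm(8); b <- stats::rnorm(8); c <- stats::rnorm(8)
    expect_equal(manhattanDist(a, b), manhattanDist(b, a))
    expect_lte(manhattanDist(a, c),
               manhattanDist(a, b) + manhattanDist(b, c) + 1e-12)
  }
  expect_error(manhattanDist(1:3, 1:4), "dimension mismatch")
})

test_that("1-NN returns the stored label for its own training rows", {
  set.seed(32)
  x <- matrix(stats::rnorm(40 * 30), 40, 30)
  labs <- sample(activityLevels(), 30, replace = TRUE)
  pred <- knnClassify(x, x, k = 1, labels = labs)
  expect_identical(pred, labs)
})

test_that("distance ties go to the lower training index", {
  # every 2-point configuration with an equidistant query
  for (labs in list(c("A", "B"), c("B", "A"))) {
    train <- cbind(c(0, 0), c(2, 0))
    pred <- knnClassify(train, c(1, 0), k = 1, labels = labs)
    expect_identical(pred, labs[1])
  }
  # vote tie at k = 2: class of the nearest tied member wins
  train <- cbind(c(0, 0), c(3, 0))
  expect_identical(knnClassify(train, c(1, 0), k = 2,
                               labels = c("A", "B")), "A")
  expect_identical(knnClassify(train, c(2.5, 0), k = 2,
                               labels = c("A", "B")), "B")
})

test_that("column order only matters where the tie-break applies", {
  set.seed(33)
  x <- matrix(stats::rnorm(10 * 60), 10, 60)      # continuous: no ties
  labs <- sample(c("1a", "2a", "3a"), 60, replace = TRUE)
  q <- matrix(stats::rnorm(10 * 15), 10, 15)
  p1 <- knnClassify(x, q, k = 3, labels = labs)
  perm <- sample(60)
  p2 <- knnClassify(x[, perm], q, k = 3, labels = labs[perm])
  expect_identical(p1, p2)
})

test_that("LOO accuracy matches the brute-force refit oracle", {
  set.seed(34)
  x <- matrix(round(stats::rnorm(6 * 30), 1), 6, 30)  # rounding forces ties
  labs <- sample(c("1a", "1b", "2a"), 30, replace = TRUE)
  got <- looSelectK(x, kCandidates = c(1, 3, 5), labels = labs)
  for (k in c(1, 3, 5))
    expect_equal(unname(got$accuracy[as.character(k)]),
                 bruteLooAccuracy(x, labs, k))
  expect_true(got$bestK %in% c(1, 3, 5))
  expect_error(looSelectK(x, kCandidates = 30, labels = labs),
               "below the dataset size")
})

test_that("duplicated class-pure clusters give LOO accuracy 1 at k = 1", {
  x <- cbind(matrix(0, 4, 5), matrix(10, 4, 5), matrix(-10, 4, 5))
  labs <- rep(c("1a", "2a", "3a"), each = 5)
  got <- looSelectK(x, kCandidates = c(1, 3), labels = labs)
  expect_equal(unname(got$accuracy["1"]), 1)
  expect_equal(got$bestK, 1L)
})

test_that("the stratified split conserves and reproduces", {
  set.seed(35)
  f <- matrix(stats::runif(5 * 120), 5, 120)
  f <- sweep(f, 2, apply(f, 2, max), "/")
  fs <- FeatureSet(f, subject = rep(c("S01", "S02"), 60),
                   activity = rep(activityLevels(), each = 10),
                   sensor = "acc")
  sp <- splitTrainTest(fs, nTrain = 60, seed = 7)
  expect_equal(ncol(sp$train) + ncol(sp$test), 120L)
  expect_equal(ncol(sp$train), 60L)
  # proportional stratification: 5 of each activity's 10 in the train set
  expect_true(all(table(activityLabels(sp$train)) == 5))
  sp2 <- splitTrainTest(fs, nTrain = 60, seed = 7)
  expect_identical(sp$trainIndex, sp2$trainIndex)
  sp3 <- splitTrainTest(fs, nTrain = 60, seed = 8)
  expect_false(identical(sp$trainIndex, sp3$trainIndex))
  expect_error(splitTrainTest(fs, nTrain = 120), "strictly between")
})

test_that("every activity reaches the train set when nTrain >= 12", {
  set.seed(36)
  f <- matrix(stats::runif(4 * 240), 4, 240)
  f <- sweep(f, 2, apply(f, 2, max), "/")
  counts <- c(5, 40, 12, 33, 25, 8, 19, 27, 14, 22, 17, 18)
  fs <- FeatureSet(f, subject = "S01",
                   activity = rep(activityLevels(), times = counts),
                   sensor = "emg")
  for (seed in 1:5) {
    sp <- splitTrainTest(fs, nTrain = 120, seed = seed)
    expect_setequal(unique(activityLabels(sp$train)), activityLevels())
  }
})
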
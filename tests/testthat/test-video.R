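test_that("grayscale conversion uses the BT.601 luminance weights", {
  g <- matrix(stats::runif(24), 4, 6)
  expect_identical(toGrayscale(g), g)
  rgb <- array(stats::runif(4 * 6 * 3), dim = c(4, 6, 3))
  want <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  expect_equal(toGrayscale(rgb), want)
  white <- array(1, dim = c(2, 2, 3))
  expect_equal(toGrayscale(white), matrix(1, 2, 2))
  # swapping channels changes the result (weights are unequal)
  swapped <- rgb[, , c(2, 1, 3)]
  expect_false(isTRUE(all.equal(toGrayscale(rgb), toGrayscale(swapped))))
  expect_error(toGrayscale(array(1, dim = c(2, 2, 4))), "channel")
})

test_that("Horn-Schunck returns zero flow for identical or flat frames", {
  f <- matrix(stats::runif(48 * 40), 40, 48)
  flow <- hornSchunck(f, f)
  expect_equal(max(abs(flow$u)), 0)
  expect_equal(max(abs(flow$v)), 0)
  flat <- matrix(0.5, 40, 48)
  flow2 <- hornSchunck(flat, flat + 0)
  expect_equal(max(abs(flow2$u)), 0)
  expect_error(hornSchunck(f, matrix(0, 10, 10)), "same shape")
})

test_that("Horn-Schunck recovers a one-pixel translation", {
  clip <- renderTranslationClip(0, speed = 1, nFrames = 2,
                                width = 96, height = 80)
  flow <- hornSchunck(clip[, , 1], clip[, , 2])
  blob <- flow$u[20:60, 28:68]
  expect_gt(mean(blob), 0.5)
  expect_lt(mean(blob), 1.5)
  expect_lt(abs(mean(flow$v[20:60, 28:68])), 0.2)
})

test_that("the brightness-constancy residual decreases over early iterations", {
  clip <- renderTranslationClip(45, speed = 1, nFrames = 2,
                                width = 64, height = 56)
  flow <- hornSchunck(clip[, , 1], clip[, , 2], trace = TRUE)
  expect_true(all(diff(flow$residuals[1:10]) < 0))
})

test_that("median filtering matches the exhaustive per-pixel oracle", {
  set.seed(42)
  u <- matrix(stats::rnorm(16 * 16), 16, 16)
  v <- matrix(stats::rnorm(16 * 16), 16, 16)
  out <- medianFilterFlow(list(u = u, v = v), size = 5)
  expect_equal(out$u, bruteMedian2d(u, 5))
  expect_equal(out$v, bruteMedian2d(v, 5))
  # constants pass through; a lone outlier is removed
  const <- list(u = matrix(2, 8, 8), v = matrix(-1, 8, 8))
  expect_equal(medianFilterFlow(const)$u, const$u)
  spike <- const
  spike$u[4, 4] <- 50
  expect_equal(medianFilterFlow(spike)$u, const$u)
})

test_that("motion binarization is a strict threshold on the magnitude", {
  flow <- list(u = matrix(c(0.1, 0.9, 0.5, 0), 2, 2),
               v = matrix(0, 2, 2))
  m <- motionMask(flow, T = 0.5)
  expect_identical(as.vector(m), c(FALSE, TRUE, FALSE, FALSE))
  expect_false(any(motionMask(flow, T = 2)))
  expect_error(motionMask(flow, T = 0), "positive")
})

test_that("the moving silhouette combines masks and fills holes", {
  ring <- matrix(FALSE, 20, 20)
  ring[5:15, 5:15] <- TRUE
  ring[8:12, 8:12] <- FALSE
  filled <- movingSilhouette(ring, ring)
  expect_true(all(filled[5:15, 5:15]))
  a <- matrix(FALSE, 10, 10); a[2:4, 2:4] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  uni <- movingSilhouette(a, b, "union")
  expect_true(all(uni[2:4, 2:4]) && all(uni[7:9, 7:9]))
  expect_false(any(movingSilhouette(a, b, "intersection")))
  expect_error(movingSilhouette(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("contour thickening leaves a 4-px inner band", {
  mask <- matrix(FALSE, 28, 28)
  mask[5:24, 5:24] <- TRUE            # 20 x 20 solid square
  band <- thickenContour(mask, width = 4)
  expect_equal(sum(band), 400 - 144)  # 20^2 - 12^2
  expect_true(all(mask[band]))
  # band and eroded interior are disjoint
  interior <- mask & !band
  expect_false(any(band & interior))
  thin <- matrix(FALSE, 12, 12); thin[6:7, 3:9] <- TRUE
  expect_equal(thickenContour(thin, 4), thin)
})

test_that("direction histograms bin, weight and normalize as specified", {
  band <- matrix(TRUE, 4, 4)
  right <- list(u = matrix(1, 4, 4), v = matrix(0, 4, 4))
  h <- directionHistogram(right, band)
  expect_equal(unname(h), c(1, rep(0, 7)))
  # eight equal-magnitude vectors at the bin centers
  ang <- seq(0, 315, by = 45) * pi / 180
  h8 <- directionHistogram(list(u = matrix(cos(ang), 1, 8),
                                v = matrix(-sin(ang), 1, 8)),
                           matrix(TRUE, 1, 8))
  expect_equal(unname(h8), rep(0.125, 8))
  # no motion: all-zero sentinel
  none <- list(u = matrix(0, 3, 3), v = matrix(0, 3, 3))
  expect_equal(unname(directionHistogram(none, matrix(TRUE, 3, 3))),
               rep(0, 8))
  # magnitude weighting matches the brute-force accumulation oracle
  set.seed(7)
  u <- matrix(stats::rnorm(64), 8, 8); v <- matrix(stats::rnorm(64), 8, 8)
  bnd <- matrix(stats::runif(64) > 0.4, 8, 8)
  got <- directionHistogram(list(u = u, v = v), bnd)
  acc <- numeric(8)
  for (i in 1:8) for (j in 1:8) if (bnd[i, j]) {
    mag <- sqrt(u[i, j]^2 + v[i, j]^2)
    deg <- (atan2(-v[i, j], u[i, j]) * 180 / pi) %% 360
    b <- floor(((deg + 22.5) %% 360) / 45) + 1
    acc[b] <- acc[b] + mag
  }
  expect_equal(unname(got), acc / sum(acc), tolerance = 1e-12)
})

test_that("rotating all flow vectors by 45 degrees permutes the bins", {
  set.seed(8)
  u <- matrix(stats::rnorm(100), 10, 10)
  v <- matrix(stats::rnorm(100), 10, 10)
  band <- matrix(TRUE, 10, 10)
  h1 <- directionHistogram(list(u = u, v = v), band)
  s <- sin(pi / 4); cs <- cos(pi / 4)
  a <- -v                       # display-space y (upward positive)
  u2 <- u * cs - a * s
  a2 <- u * s + a * cs
  h2 <- directionHistogram(list(u = u2, v = -a2), band)
  expect_equal(unname(h2[c(2:8, 1)]), unname(h1), tolerance = 1e-9)
})

test_that("the video descriptor has dimension (N - 2) x 8", {
  clip <- renderTranslationClip(0, speed = 1.2, nFrames = 6,
                                width = 64, height = 56)
  f <- buildVideoFeature(clip)
  expect_length(f, 4 * 8)
  expect_equal(max(f), 1)
  expect_true(all(f >= 0))
  expect_error(buildVideoFeature(clip[, , 1:2]), "3 frames")
})

test_that("a static clip raises the degenerate-vector error", {
  stand <- renderSilhouetteVideo("stand", 0.3, tinyConfig())
  expect_error(buildVideoFeature(stand), "degenerate")
})

test_that("a right-translating blob concentrates every histogram in B1", {
  clip <- renderTranslationClip(0, speed = 1.2, nFrames = 6,
                                width = 64, height = 56)
  f <- matrix(buildVideoFeature(clip), ncol = 8, byrow = TRUE)
  for (r in seq_len(nrow(f)))
    expect_equal(which.max(f[r, ]), 1L)
  # every per-frame histogram was normalized before concatenation, so all
  # rows carry the same total mass after the global rescaling
  expect_true(all(abs(rowSums(f) - rowSums(f)[1]) < 1e-9))
})
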
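# Shared fixtures and independent oracles for the test suite.

# Tiny cohort configurations keep unit tests fast; video frames are small
# and biosignal rates are the real ones.
tinyConfig <- function(seed = 5, ...) {
  cohortConfig(nSubjects = 2, repsRange = c(3, 3), seed = seed,
               videoSize = c(48, 48), ...)
}

noiselessConfig <- function(seed = 9, ...) {
  cohortConfig(nSubjects = 1, repsRange = c(3, 3), seed = seed,
               durationSdlog = 0,
               noiseSd = c(emg = 0, pressure = 0, acc = 0, video = 0),
               subjectScaleSd = 0, videoSize = c(48, 48), ...)
}

# Brute-force k-NN with the documented tie rules, built on stats::dist for
# the distances (an independent route from the package's colSums kernel).
bruteKnn <- function(train, labels, query, k) {
  d <- as.numeric(stats::dist(rbind(t(query), t(train)),
                              method = "manhattan"))[seq_len(ncol(train))]
  d <- signif(d, 12)                 # the documented tie-detection snap
  ord <- order(d, seq_along(d))      # explicit stable order
  nb <- ord[seq_len(k)]
  votes <- labels[nb]
  counts <- table(votes)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1L) tied else votes[votes %in% tied][1L]
}

bruteLooAccuracy <- function(x, labels, k) {
  n <- ncol(x)
  hits <- vapply(seq_len(n), function(i)
    bruteKnn(x[, -i, drop = FALSE], labels[-i], x[, i], k) == labels[i],
    logical(1L))
  mean(hits)
}

# Exhaustive per-pixel median with shrinking borders, via stats::median.
bruteMedian2d <- function(m, size) {
  h <- size %/% 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ri <- max(1, i - h):min(nrow(m), i + h)
    rj <- max(1, j - h):min(ncol(m), j + h)
    out[i, j] <- stats::median(m[ri, rj])
  }
  out
}

# A deterministic multi-channel clip with the given rate attribute.
makeClip <- function(nSamples, nChannels, rate, fun = function(t, ch)
  (0.2 + 0.1 * ch) * (1 + sin(2 * pi * 1.3 * t + ch))) {
  t <- (seq_len(nSamples) - 1) / rate
  x <- vapply(seq_len(nChannels), function(ch) fun(t, ch),
              numeric(nSamples))
  clip <- matrix(x, nSamples, nChannels)
  attr(clip, "rate") <- rate
  clip
}

makeNormalizer <- function(emgMax = 1, pressureMax = 1, accMax = 1,
                           accOffset = c(0, 0, 0)) {
  new("SubjectNormalizer", subjectId = "S01", emgMax = emgMax,
      pressureMax = pressureMax, accMax = accMax, accOffset = accOffset)
}
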
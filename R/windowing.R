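#' @include AllClasses.R
NULL

#' Window specification
#'
#' The analysis normalizes data length across activities and subjects by
#' cutting a fixed window of width `W` from every labeled repetition. The
#' default `W = 1.6` s is the standard choice: the shortest window that
#' covers the bulk of the pooled duration histogram. By default the window
#' is centered on the segment midpoint, so repetitions shorter than `W` are
#' flanked symmetrically by context; `alignment = "start"` anchors it at the
#' segment start instead.
#'
#' @param W window width in seconds (> 0).
#' @param alignment `"center"` (default) or `"start"`.
#' @return A list with class `"WindowSpec"`.
#' @examples
#' windowSpec()
#' @export
windowSpec <- function(W = 1.6, alignment = c("center", "start")) {
  if (!is.numeric(W) || W <= 0) stop("'W' must be a positive duration")
  structure(list(W = W, alignment = match.arg(alignment)),
            class = "WindowSpec")
}

#' @export
print.WindowSpec <- function(x, ...) {
  cat(sprintf("WindowSpec: W = %g s, %s-aligned\n", x$W, x$alignment))
  invisible(x)
}

.checkSegments <- function(segments) {
  need <- c("subject", "activity", "t_start", "t_end")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop("a segment table needs columns ", paste(need, collapse = ", "))
  if (nrow(segments) == 0L) stop("the segment table is empty")
  if (any(segments$t_end <= segments$t_start))
    stop("every segment must have t_end > t_start")
  bad <- setdiff(unique(segments$activity), activityLevels())
  if (length(bad))
    stop("unknown activity labels: ", paste(bad, collapse = ", "))
  invisible(segments)
}

#' Performance-time histograms of a segment table
#'
#' Computes the histogram family used to choose the window width `W`:
#' `MIN`, `MAX` and `AVG` histograms of the per-(subject, activity)
#' minimal/maximal/average repetition duration, the pooled `ALL` histogram
#' with one value per repetition, and one histogram per activity. Bins are
#' left-closed intervals `[left, right)` of width `binWidth` starting at 0.
#'
#' @param segments a segment table (columns subject, activity, t_start,
#'   t_end).
#' @param binWidth histogram bin width in seconds (default 0.1).
#' @return A data.frame with columns `histogram` (MIN/MAX/AVG/ALL or an
#'   activity label), `bin_left`, `bin_right`, `count`.
#' @examples
#' segs <- data.frame(subject = "S01", activity = "1a",
#'                    t_start = c(0, 5, 10), t_end = c(1, 7, 13))
#' h <- durationHistograms(segs, binWidth = 0.5)
#' subset(h, histogram == "AVG" & count > 0)
#' @export
durationHistograms <- function(segments, binWidth = 0.1) {
  .checkSegments(segments)
  if (!is.numeric(binWidth) || binWidth <= 0)
    stop("'binWidth' must be positive")
  dur <- segments$t_end - segments$t_start

  groups <- interaction(segments$subject, segments$activity, drop = TRUE)
  perGroup <- data.frame(
    min = tapply(dur, groups, min),
    max = tapply(dur, groups, max),
    avg = tapply(dur, groups, mean))

  maxVal <- max(dur)
  nBins <- as.integer(ceiling(maxVal / binWidth + 1e-9)) + 1L
  left <- (seq_len(nBins) - 1L) * binWidth
  binOf <- function(v) pmin(floor(v / binWidth + 1e-9) + 1L, nBins)
  oneHist <- function(name, v)
    data.frame(histogram = name, bin_left = left,
               bin_right = left + binWidth,
               count = tabulate(binOf(v), nbins = nBins))

  out <- rbind(oneHist("MIN", perGroup$min),
               oneHist("MAX", perGroup$max),
               oneHist("AVG", perGroup$avg),
               oneHist("ALL", dur))
  for (a in intersect(activityLevels(), unique(segments$activity)))
    out <- rbind(out, oneHist(a, dur[segments$activity == a]))
  rownames(out) <- NULL
  out
}

#' Cut a fixed-width window from one sensor's stream
#'
#' Extracts exactly `round(W * rate)` samples per channel (for video,
#' `round(W * fps)` frames) around a labeled segment. The clip sample count
#' depends only on the window width and the sampling rate, never on the
#' segment duration: longer segments are truncated to a contiguous sub-span
#' and shorter ones are padded by their surrounding recording context.
#'
#' @param recording a [MultiSensorRecording-class].
#' @param segment a one-row segment (list or data.frame row with `t_start`,
#'   `t_end`).
#' @param sensor one of `"emg"`, `"pressure"`, `"acc"`, `"video"`.
#' @param spec a [windowSpec()].
#' @return For biosignals, a samples-by-channels matrix with attributes
#'   `rate` and `tStart`; for video, a `height x width x frames` array with
#'   the same attributes.
#' @examples
#' cohort <- generateCohort(cohortConfig(nSubjects = 1, repsRange = c(2, 2),
#'                                       videoSize = c(64, 48), seed = 3))
#' clip <- extractWindow(cohort$recordings[[1]], cohort$segments[1, ], "acc")
#' dim(clip)  # 160 samples x 3 channels for W = 1.6 s at 100 Hz
#' @export
extractWindow <- function(recording, segment, sensor = c("emg", "pressure",
                                                         "acc", "video"),
                          spec = windowSpec()) {
  sensor <- match.arg(sensor)
  stopifnot(is(recording, "MultiSensorRecording"))
  tStart <- segment$t_start
  tEnd <- segment$t_end
  if (is.null(tStart) || is.null(tEnd) || tEnd <= tStart)
    stop("'segment' must provide t_start < t_end")
  rate <- samplingRates(recording)[[sensor]]
  t0 <- switch(spec$alignment,
               center = (tStart + tEnd) / 2 - spec$W / 2,
               start = tStart)
  n <- round(spec$W * rate)
  if (n < 1L) stop("window shorter than one sample period")
  i0 <- floor(t0 * rate + 1e-9) + 1
  total <- if (sensor == "video") nFrames(videoStream(recording))
           else nrow(slot(recording, sensor))
  if (i0 < 1 || i0 + n - 1 > total)
    stop(sprintf(
      "window [%.2f, %.2f] s lies outside the recorded span of sensor '%s'",
      t0, t0 + spec$W, sensor))
  idx <- seq.int(i0, length.out = n)
  out <- if (sensor == "video") getFrames(videoStream(recording), idx)
         else slot(recording, sensor)[idx, , drop = FALSE]
  attr(out, "rate") <- rate
  attr(out, "tStart") <- (i0 - 1) / rate
  out
}
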
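#' @include AllClasses.R windowing.R
NULL

#' Full-wave rectification
#'
#' Elementwise absolute value, the first step of the EMG envelope chain.
#'
#' @param signal numeric vector or matrix of finite values.
#' @return Object of the same shape.
#' @examples
#' rectify(c(-1, 2, -3))
#' @export
rectify <- function(signal) {
  if (any(!is.finite(signal))) stop("'signal' must be finite")
  abs(signal)
}

#' Centered moving average with shrinking edges
#'
#' Smooths each channel with a centered moving mean over
#' `round(widthS * rate)` samples. At the boundaries the window shrinks to
#' the available samples, so the output has the input's length and constant
#' signals pass through unchanged. For even window sizes the window extends
#' one sample further to the right of the center.
#'
#' @param signal numeric vector, or matrix smoothed column-wise.
#' @param widthS window width in seconds.
#' @param rate sampling rate in Hz; `widthS * rate` must be at least 1.
#' @return Smoothed object of the same shape.
#' @examples
#' movingAverage(c(0, 0, 4, 0, 0), widthS = 3, rate = 1)
#' @export
movingAverage <- function(signal, widthS, rate) {
  k <- round(widthS * rate)
  if (k < 1L) stop("moving-average window is shorter than one sample period")
  if (is.matrix(signal))
    return(apply(signal, 2L, movingAverage, widthS = widthS, rate = rate))
  n <- length(signal)
  lo <- (k - 1L) %/% 2L
  hi <- k - 1L - lo
  cs <- cumsum(c(0, signal))
  iLo <- pmax(seq_len(n) - lo, 1L)
  iHi <- pmin(seq_len(n) + hi, n)
  (cs[iHi + 1L] - cs[iLo]) / (iHi - iLo + 1L)
}

#' Divide by the subject's global sensor maximum
#'
#' Subject-wise amplitude normalization: the signal is divided by that
#' subject's stored maximum over all measurements of all activities for the
#' given sensor, making amplitudes comparable across subjects.
#'
#' @param signal numeric vector or matrix.
#' @param normalizer a [SubjectNormalizer-class].
#' @param sensor `"emg"`, `"pressure"` or `"acc"`.
#' @return The scaled signal.
#' @seealso [computeNormalizer()]
#' @export
subjectMaxNormalize <- function(signal, normalizer,
                                sensor = c("emg", "pressure", "acc")) {
  sensor <- match.arg(sensor)
  stopifnot(is(normalizer, "SubjectNormalizer"))
  mx <- slot(normalizer, paste0(sensor, "Max"))
  if (!is.finite(mx) || mx <= 0)
    stop("degenerate subject: stored maximum for sensor '", sensor,
         "' is not strictly positive")
  signal / mx
}

#' Scale a vector so its maximum is one
#'
#' Amplitude normalization into the unit interval: division by the vector's
#' own maximum. Requires at least one strictly positive value; afterwards
#' the maximum is exactly 1 (exact zeros may remain, e.g. a silent EMG
#' channel).
#'
#' @param vector numeric vector or matrix.
#' @return The scaled object, with `max(.) == 1`.
#' @examples
#' unitIntervalNormalize(c(2, 4))
#' @export
unitIntervalNormalize <- function(vector) {
  mx <- max(vector)
  if (!is.finite(mx) || mx <= 0)
    stop("degenerate vector: no strictly positive value to normalize by")
  vector / mx
}

#' Resample a uniformly sampled signal by linear interpolation
#'
#' Downsamples to `rateOut` (default 25 Hz) by linear interpolation at the
#' target timestamps `k / rateOut`; the output has
#' `round(duration * rateOut)` samples. No anti-alias filter is applied: the
#' preceding moving averages already smooth the signal. Upsampling is not
#' supported.
#'
#' @param signal numeric vector, or matrix resampled column-wise.
#' @param rateIn input sampling rate in Hz (>= `rateOut`).
#' @param rateOut output rate in Hz (default 25).
#' @return The resampled object.
#' @examples
#' length(resampleSignal(rep(5, 160), rateIn = 100))  # 40 samples at 25 Hz
#' @export
resampleSignal <- function(signal, rateIn, rateOut = 25) {
  if (rateIn < rateOut)
    stop("upsampling is unsupported: rateIn must be at least ", rateOut,
         " Hz")
  if (is.matrix(signal))
    return(apply(signal, 2L, resampleSignal, rateIn = rateIn,
                 rateOut = rateOut))
  n <- length(signal)
  m <- round(n / rateIn * rateOut)
  tIn <- (seq_len(n) - 1L) / rateIn
  tOut <- (seq_len(m) - 1L) / rateOut
  stats::approx(tIn, signal, xout = tOut, rule = 2)$y
}

#' Average pressure sensels into the six foot regions
#'
#' Reduces the 64 sensel values to the six region means L1, L2, L3, R1, R2,
#' R3 (heel, center, front of the left and right foot).
#'
#' @param frame numeric vector of 64 sensel values, or a samples-by-64
#'   matrix.
#' @param layout integer vector of length 64 assigning each sensel to a
#'   region 1..6; default [defaultPressureLayout()].
#' @return Named numeric of length 6, or a samples-by-6 matrix.
#' @examples
#' pressureRegionAverage(rep(2, 64))
#' @export
pressureRegionAverage <- function(frame, layout = defaultPressureLayout()) {
  if (length(layout) != 64L || anyNA(layout) ||
      !all(sort(unique(as.integer(layout))) == 1:6))
    stop("'layout' must assign each of the 64 sensels to one of 6 regions")
  vec <- !is.matrix(frame)
  if (vec) frame <- matrix(frame, nrow = 1L)
  if (ncol(frame) != 64L) stop("a pressure frame has exactly 64 sensels")
  ind <- outer(as.integer(layout), 1:6, "==") * 1
  out <- (frame %*% ind) %*% diag(1 / colSums(ind))
  colnames(out) <- .pressureRegions
  if (vec) out[1L, ] else out
}

#' Subtract accelerometer channel offsets
#'
#' Removes the per-channel offsets (including the gravity component)
#' estimated from the stationary lead-in, centering the stationary signal
#' at zero.
#'
#' @param signalXyz samples-by-3 matrix (X, Y, Z).
#' @param offsets numeric length-3 offsets, e.g. from [computeNormalizer()].
#' @return The offset-corrected matrix.
#' @export
accRemoveOffset <- function(signalXyz, offsets) {
  if (!is.matrix(signalXyz) || ncol(signalXyz) != 3L)
    stop("'signalXyz' must be a samples-by-3 matrix")
  if (length(offsets) != 3L || any(!is.finite(offsets)))
    stop("'offsets' must be 3 finite values (is the 10 s lead-in missing?)")
  sweep(signalXyz, 2L, offsets, "-")
}

#' Per-subject normalization constants from a full recording
#'
#' Computes the subject's amplitude references: the accelerometer offsets
#' (per-channel mean over the first 10 s stationary lead-in) and, per
#' sensor, the maximum over the subject's whole recording after that
#' sensor's rectification/averaging pre-steps (rectified + 0.1 s-smoothed
#' EMG; region-averaged + 0.3 s-smoothed pressure; offset-corrected +
#' 0.2 s-smoothed acceleration, in absolute value).
#'
#' @param recording a [MultiSensorRecording-class].
#' @param emgSmooth,pressureSmooth,accSmooth moving-average widths in
#'   seconds (defaults 0.1, 0.3, 0.2).
#' @param layout pressure sensel layout, see [defaultPressureLayout()].
#' @return A [SubjectNormalizer-class].
#' @export
computeNormalizer <- function(recording, emgSmooth = 0.1,
                              pressureSmooth = 0.3, accSmooth = 0.2,
                              layout = defaultPressureLayout()) {
  stopifnot(is(recording, "MultiSensorRecording"))
  rates <- samplingRates(recording)
  if (recording@leadIn < 10) stop("missing 10 s stationary lead-in")

  emgEnv <- movingAverage(rectify(emgSignal(recording)), emgSmooth,
                          rates[["emg"]])
  press <- movingAverage(pressureRegionAverage(pressureSignal(recording),
                                               layout),
                         pressureSmooth, rates[["pressure"]])
  acc <- accSignal(recording)
  nLead <- floor(10 * rates[["acc"]])
  offsets <- colMeans(acc[seq_len(nLead), , drop = FALSE])
  accS <- movingAverage(accRemoveOffset(acc, offsets), accSmooth,
                        rates[["acc"]])
  new("SubjectNormalizer", subjectId = subjectId(recording),
      emgMax = max(emgEnv), pressureMax = max(press),
      accMax = max(abs(accS)), accOffset = as.numeric(offsets))
}

#' Build one biosignal feature vector
#'
#' Applies a sensor's full processing chain to a fixed-width clip, in fixed
#' order:
#' \describe{
#'   \item{emg (sensor B)}{rectify, 0.1 s moving average, divide by the
#'     subject's EMG maximum, amplitude normalization to the unit interval
#'     over the concatenated 8 channels, resample each channel to 25 Hz,
#'     concatenate EL1..EL4, ER1..ER4.}
#'   \item{pressure (sensor C)}{average sensels into the 6 regions, 0.3 s
#'     moving average, subject normalization, unit-interval normalization,
#'     25 Hz resampling, concatenate L1..L3, R1..R3.}
#'   \item{acc (sensor E)}{subtract the lead-in offsets, 0.2 s moving
#'     average, subject normalization, unit-interval normalization, 25 Hz
#'     resampling, concatenate X, Y, Z.}
#' }
#' The amplitude is normalized before resampling, so after interpolation the
#' maximum can fall marginally below 1; it is not re-normalized. The result
#' has `n_channels * round(25 * W)` entries: 320 (EMG), 240 (pressure) or
#' 120 (acc) for the default `W = 1.6` s.
#'
#' @param clip a clip from [extractWindow()] (attribute `rate` required).
#' @param sensor `"emg"`, `"pressure"` or `"acc"`.
#' @param normalizer the subject's [SubjectNormalizer-class].
#' @param emgSmooth,pressureSmooth,accSmooth moving-average widths (s).
#' @param resampleRate classifier input rate, default 25 Hz.
#' @param layout pressure sensel layout.
#' @return Numeric feature vector.
#' @export
buildBiosignalFeature <- function(clip,
                                  sensor = c("emg", "pressure", "acc"),
                                  normalizer,
                                  emgSmooth = 0.1, pressureSmooth = 0.3,
                                  accSmooth = 0.2, resampleRate = 25,
                                  layout = defaultPressureLayout()) {
  sensor <- match.arg(sensor)
  rate <- attr(clip, "rate")
  if (is.null(rate)) stop("'clip' must carry a 'rate' attribute")
  x <- switch(sensor,
    emg = movingAverage(rectify(clip), emgSmooth, rate),
    pressure = movingAverage(pressureRegionAverage(unclass(clip), layout),
                             pressureSmooth, rate),
    acc = movingAverage(accRemoveOffset(unclass(clip),
                                        normalizer@accOffset),
                        accSmooth, rate))
  x <- subjectMaxNormalize(x, normalizer, sensor)
  x <- unitIntervalNormalize(x)
  as.numeric(resampleSignal(x, rateIn = rate, rateOut = resampleRate))
}
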
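#' The twelve elementary activity labels
#'
#' The study design uses six movement families, each split into a forward
#' phase (`a`) and its return phase (`b`): 1 squat down / up, 2 sit down /
#' stand up from a chair, 3 reach the arm forward / return, 4 reach the arm
#' upward / return, 5 bend the trunk forward / straighten, 6 single step
#' with the right / left leg.
#'
#' @return Character vector of the 12 labels `"1a"` ... `"6b"`.
#' @examples
#' activityLevels()
#' @export
activityLevels <- function() {
  as.vector(t(outer(1:6, c("a", "b"), paste0)))
}

.sensorIds <- c(emg = "B", pressure = "C", video = "D", acc = "E")
.sensorNames <- c("emg", "pressure", "acc", "video")

#' CohortConfig: parameters of the synthetic multi-sensor cohort
#'
#' Holds every knob of the synthetic study: cohort size, repetition counts,
#' per-activity duration models, per-sensor noise scales, inter-subject
#' amplitude spread, sampling rates and video geometry. The defaults encode
#' the study conditions the analysis assumes: 20 subjects, 12 activities,
#' 19--46 repetitions each, 8-channel EMG at 2 kHz, 64-sensel plantar
#' pressure at 100 Hz, triaxial sternum acceleration at 100 Hz (with a 10 s
#' stationary lead-in used for offset estimation), and 25 fps grayscale
#' silhouette video.
#'
#' @slot nSubjects number of subjects.
#' @slot activities the 12 activity labels.
#' @slot repsRange integer interval (min, max) of repetitions per activity.
#' @slot durationMedians named numeric, median repetition duration (s) per
#'   activity; repetition durations are log-normal around these medians.
#' @slot durationSdlog log-scale sd of repetition durations.
#' @slot noiseSd named numeric (emg, pressure, acc, video): additive Gaussian
#'   noise sd per sensor, in the archetype's amplitude units (video: intensity
#'   units on `[0, 1]`).
#' @slot subjectScaleSd log-scale sd of the per-subject, per-sensor amplitude
#'   multiplier.
#' @slot seed integer RNG seed; equal seeds give byte-identical cohorts.
#' @slot videoSize integer (width, height) of a video frame in pixels.
#' @slot emgRate,pressureRate,accRate,videoRate sampling rates in Hz (video:
#'   frames per second).
#' @slot leadIn stationary lead-in duration (s), at least 10.
#' @slot gap rest gap between consecutive repetitions (s).
#' @slot tailPad trailing stationary padding (s).
#' @seealso [cohortConfig()] for the user-facing constructor.
#' @export
setClass("CohortConfig", representation(
  nSubjects = "integer",
  activities = "character",
  repsRange = "integer",
  durationMedians = "numeric",
  durationSdlog = "numeric",
  noiseSd = "numeric",
  subjectScaleSd = "numeric",
  seed = "integer",
  videoSize = "integer",
  emgRate = "numeric",
  pressureRate = "numeric",
  accRate = "numeric",
  videoRate = "numeric",
  leadIn = "numeric",
  gap = "numeric",
  tailPad = "numeric"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@activities) != 12L ||
      !setequal(object@activities, activityLevels()))
    msg <- c(msg, "'activities' must be exactly the 12 labels 1a..6b")
  if (length(object@repsRange) != 2L || any(object@repsRange < 1L) ||
      any(object@repsRange > 100L) ||
      object@repsRange[1L] > object@repsRange[2L])
    msg <- c(msg, "'repsRange' must be an increasing interval within [1, 100]")
  rates <- c(object@emgRate, object@pressureRate, object@accRate,
             object@videoRate)
  if (any(!is.finite(rates)) || any(rates <= 0))
    msg <- c(msg, "all sampling rates must be positive")
  if (object@nSubjects < 1L)
    msg <- c(msg, "'nSubjects' must be at least 1")
  if (!all(c("emg", "pressure", "acc", "video") %in% names(object@noiseSd)))
    msg <- c(msg, "'noiseSd' must name emg, pressure, acc and video")
  if (any(object@noiseSd < 0))
    msg <- c(msg, "'noiseSd' must be non-negative")
  if (!setequal(names(object@durationMedians), object@activities))
    msg <- c(msg, "'durationMedians' must be named by the activity labels")
  if (any(object@durationMedians <= 0))
    msg <- c(msg, "'durationMedians' must be positive")
  if (length(object@videoSize) != 2L || any(object@videoSize < 16L))
    msg <- c(msg, "'videoSize' must be (width, height), each at least 16 px")
  if (object@leadIn < 10)
    msg <- c(msg, "'leadIn' must be at least 10 s (offset estimation)")
  if (length(msg)) msg else TRUE
})

#' SilhouetteVideo: a lazily rendered grayscale frame stream
#'
#' Frames are synthesized on demand by a deterministic renderer closure, so a
#' full recording session never has to be materialized in memory. Frame `k`
#' covers time `(k - 1) / fps` seconds from the start of the recording.
#'
#' @slot width,height frame size in pixels.
#' @slot fps frames per second.
#' @slot nFrames total number of frames in the stream.
#' @slot renderer `function(idx)` returning an `height x width x length(idx)`
#'   array of intensities in `[0, 1]` for the requested frame indices.
#' @export
setClass("SilhouetteVideo", representation(
  width = "integer",
  height = "integer",
  fps = "numeric",
  nFrames = "integer",
  renderer = "function"
))

setValidity("SilhouetteVideo", function(object) {
  if (object@fps <= 0) return("'fps' must be positive")
  if (object@nFrames < 0) return("'nFrames' must be non-negative")
  TRUE
})

#' MultiSensorRecording: one subject's synchronized raw streams
#'
#' All four streams cover the same time span, beginning with a stationary
#' lead-in of at least 10 seconds (the subject stands still; the lead-in is
#' used to estimate accelerometer offsets). Signals are stored with time in
#' rows and channels in columns.
#'
#' @slot subjectId subject identifier.
#' @slot emg numeric matrix, 8 columns `EL1..EL4, ER1..ER4` (left/right
#'   quadriceps, biceps femoris, tibialis anterior, gastrocnemius).
#' @slot pressure numeric matrix, 64 columns (32 sensels per foot).
#' @slot acc numeric matrix, 3 columns `X, Y, Z`.
#' @slot video a [SilhouetteVideo-class] stream.
#' @slot rates named numeric sampling rates (emg, pressure, acc, video).
#' @slot leadIn stationary lead-in duration in seconds.
#' @export
setClass("MultiSensorRecording", representation(
  subjectId = "character",
  emg = "matrix",
  pressure = "matrix",
  acc = "matrix",
  video = "SilhouetteVideo",
  rates = "numeric",
  leadIn = "numeric"
))

setValidity("MultiSensorRecording", function(object) {
  msg <- character()
  if (ncol(object@emg) != 8L) msg <- c(msg, "emg must have exactly 8 channels")
  if (ncol(object@pressure) != 64L)
    msg <- c(msg, "pressure must have exactly 64 sensels")
  if (ncol(object@acc) != 3L) msg <- c(msg, "acc must have exactly 3 channels")
  if (!all(c("emg", "pressure", "acc", "video") %in% names(object@rates)))
    msg <- c(msg, "'rates' must name emg, pressure, acc and video")
  else if (any(object@rates <= 0))
    msg <- c(msg, "all sampling rates must be positive")
  if (object@leadIn < 10)
    msg <- c(msg, "stationary lead-in must be at least 10 s")
  if (length(msg)) msg else TRUE
})

#' SubjectNormalizer: per-subject amplitude references
#'
#' Caches, for one subject, the maxima used for subject-wise amplitude
#' normalization (taken over all of that subject's measurements of all
#' activities, after the sensor's rectification/averaging pre-steps) and the
#' per-channel accelerometer offsets (the mean over the 10 s stationary
#' lead-in).
#'
#' @slot subjectId subject identifier.
#' @slot emgMax,pressureMax,accMax positive per-sensor maxima.
#' @slot accOffset numeric length-3 accelerometer offsets (X, Y, Z).
#' @seealso [computeNormalizer()]
#' @export
setClass("SubjectNormalizer", representation(
  subjectId = "character",
  emgMax = "numeric",
  pressureMax = "numeric",
  accMax = "numeric",
  accOffset = "numeric"
))

setValidity("SubjectNormalizer", function(object) {
  msg <- character()
  if (any(c(object@emgMax, object@pressureMax, object@accMax) <= 0))
    msg <- c(msg, "per-sensor maxima must be strictly positive")
  if (length(object@accOffset) != 3L || any(!is.finite(object@accOffset)))
    msg <- c(msg, "'accOffset' must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' FeatureSet: labeled per-segment feature vectors for one sensor
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' wrapper: the single assay `"features"` holds one fixed-length feature
#' vector per column (one column per activity repetition), `colData` carries
#' the subject id and the performed activity label, and the sensor identity
#' (`emg`/`pressure`/`acc`/`video`, study codes B/C/E/D) lives in
#' `metadata(x)$sensor`. Feature values are max-normalized: the amplitude is
#' scaled into the unit interval before the final 25 Hz resampling, so values
#' never exceed 1 and every column has a strictly positive maximum.
#'
#' @seealso [FeatureSet()], [buildFeatureSet()]
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject", "activity") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'subject' and 'activity' columns")
  sens <- S4Vectors::metadata(object)$sensor
  if (is.null(sens) || !sens %in% .sensorNames)
    msg <- c(msg, "metadata()$sensor must be one of emg, pressure, acc, video")
  if (ncol(object) > 0L) {
    f <- SummarizedExperiment::assay(object, "features")
    if (any(!is.finite(f))) {
      msg <- c(msg, "features must be finite")
    } else {
      cmax <- apply(f, 2L, max)
      if (any(f > 1 + 1e-9) || any(cmax <= 0))
        msg <- c(msg,
          "features must be max-normalized: values <= 1, column max > 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: column-normalized recognition-error matrix
#'
#' Entry (recognized `r`, performed `p`) is the percentage of repetitions of
#' performed activity `p` that the classifier recognized as `r`; each column
#' sums to 100 before any display rounding, and the diagonal equals the
#' per-activity recognition correctness.
#'
#' @slot percent numeric matrix of percentages (rows = recognized,
#'   columns = performed).
#' @slot counts integer matrix of the underlying repetition counts.
#' @seealso [buildConfusion()]
#' @export
setClass("ConfusionMatrix", representation(
  percent = "matrix",
  counts = "matrix"
))

setValidity("ConfusionMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@percent), dim(object@counts)))
    msg <- c(msg, "'percent' and 'counts' must have identical shape")
  if (nrow(object@percent) != ncol(object@percent))
    msg <- c(msg, "confusion matrix must be square")
  cs <- colSums(object@percent)
  if (any(abs(cs - 100) > 1e-6))
    msg <- c(msg, "every column must sum to 100%")
  if (length(msg)) msg else TRUE
})

#' RecognitionReport: recognition correctness and dispersion statistics
#'
#' Per-sensor summary of a prediction set. For each activity `a` the report
#' holds the recognition correctness `R_a` (percent of correctly identified
#' repetitions pooled over subjects) together with its inter-subject
#' dispersion `U_a`, a weighted standard deviation of per-subject rates
#' around `R_a` with weights equal to each subject's repetition count.
#' Per subject `V` it holds the analogous `R_V` and the inter-activity
#' dispersion `U_V`. The overall entries are the pooled rate `R_all`, its
#' subject-weighted dispersion `U_all` and the activity-weighted dispersion
#' `U_act_all`.
#'
#' @slot sensor sensor name (emg, pressure, acc or video).
#' @slot perActivity data.frame with columns activity, R, U, P (correct
#'   count), W (total count), n (number of contributing subjects).
#' @slot perSubject data.frame with columns subject, R, U, P, W, m (number
#'   of contributing activities).
#' @slot overall named numeric: R_all, U_all, U_act_all, P_all, W_all.
#' @seealso [buildReport()]
#' @export
setClass("RecognitionReport", representation(
  sensor = "character",
  perActivity = "data.frame",
  perSubject = "data.frame",
  overall = "numeric"
))

setValidity("RecognitionReport", function(object) {
  msg <- character()
  R <- c(object@perActivity$R, object@perSubject$R, object@overall["R_all"])
  R <- R[!is.na(R)]
  if (any(R < 0 | R > 100))
    msg <- c(msg, "recognition rates must lie in [0, 100]")
  U <- c(object@perActivity$U, object@perSubject$U,
         object@overall[c("U_all", "U_act_all")])
  if (any(U[!is.na(U)] < 0))
    msg <- c(msg, "dispersions must be non-negative")
  if (length(msg)) msg else TRUE
})
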
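#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a cohort configuration
#'
#' All arguments default to the study conditions of the multi-sensor
#' experiment being emulated; see [CohortConfig-class] for their meaning.
#' Median repetition durations default to activity-specific values between
#' 1.3 and 2.2 s so that the bulk of the pooled duration histogram sits below
#' 2 s and the standard 1.6 s analysis window covers most repetitions.
#'
#' @param nSubjects number of subjects (default 20).
#' @param repsRange integer interval of per-activity repetition counts
#'   (default `c(19, 46)`).
#' @param durationMedians named numeric of median durations (s) per activity.
#' @param durationSdlog log-scale duration spread (default 0.18).
#' @param noiseSd named additive noise scales per sensor.
#' @param subjectScaleSd log-scale spread of subject amplitude multipliers.
#' @param seed RNG seed.
#' @param videoSize frame size as (width, height) pixels; default 180 x 144,
#'   a desk-scale stand-in for full 720 x 576 PAL frames.
#' @param emgRate,pressureRate,accRate,videoRate sampling rates (Hz / fps).
#' @param leadIn stationary lead-in (s, >= 10); @param gap rest gap between
#'   repetitions (s); @param tailPad trailing stationary padding (s).
#' @return A validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nSubjects = 2, repsRange = c(3, 3), seed = 7)
#' cfg
#' @export
cohortConfig <- function(nSubjects = 20,
                         repsRange = c(19, 46),
                         durationMedians = NULL,
                         durationSdlog = 0.18,
                         noiseSd = c(emg = 0.05, pressure = 0.03,
                                     acc = 0.03, video = 0.005),
                         subjectScaleSd = 0.15,
                         seed = 1,
                         videoSize = c(180, 144),
                         emgRate = 2000,
                         pressureRate = 100,
                         accRate = 100,
                         videoRate = 25,
                         leadIn = 10,
                         gap = 1,
                         tailPad = 2) {
  if (is.null(durationMedians)) {
    durationMedians <- c("1a" = 1.8, "1b" = 1.6, "2a" = 2.0, "2b" = 1.8,
                         "3a" = 1.5, "3b" = 1.4, "4a" = 1.6, "4b" = 1.5,
                         "5a" = 2.2, "5b" = 2.0, "6a" = 1.3, "6b" = 1.3)
  }
  new("CohortConfig",
      nSubjects = as.integer(nSubjects),
      activities = activityLevels(),
      repsRange = as.integer(repsRange),
      durationMedians = durationMedians,
      durationSdlog = durationSdlog,
      noiseSd = noiseSd,
      subjectScaleSd = subjectScaleSd,
      seed = as.integer(seed),
      videoSize = as.integer(videoSize),
      emgRate = emgRate, pressureRate = pressureRate,
      accRate = accRate, videoRate = videoRate,
      leadIn = leadIn, gap = gap, tailPad = tailPad)
}

#' Construct a FeatureSet
#'
#' @param features numeric matrix, one feature vector per column.
#' @param subject character/factor of subject ids, one per column.
#' @param activity character/factor of activity labels, one per column.
#' @param sensor one of `"emg"`, `"pressure"`, `"acc"`, `"video"`.
#' @return A [FeatureSet-class] object.
#' @examples
#' f <- matrix(runif(20), 5, 4); f <- sweep(f, 2, apply(f, 2, max), "/")
#' FeatureSet(f, subject = rep("S01", 4),
#'            activity = c("1a", "1b", "2a", "2b"), sensor = "acc")
#' @export
FeatureSet <- function(features, subject, activity, sensor) {
  sensor <- match.arg(sensor, .sensorNames)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = as.matrix(features)),
    colData = S4Vectors::DataFrame(subject = as.character(subject),
                                   activity = as.character(activity)),
    metadata = list(sensor = sensor))
  new("FeatureSet", se)
}

#' @describeIn MultiSensorRecording-class the subject identifier.
#' @param x a `MultiSensorRecording`.
#' @export
setMethod("subjectId", "MultiSensorRecording", function(x) x@subjectId)

#' @describeIn MultiSensorRecording-class the 8-channel EMG matrix.
#' @export
setMethod("emgSignal", "MultiSensorRecording", function(x) x@emg)

#' @describeIn MultiSensorRecording-class the 64-sensel pressure matrix.
#' @export
setMethod("pressureSignal", "MultiSensorRecording", function(x) x@pressure)

#' @describeIn MultiSensorRecording-class the triaxial acceleration matrix.
#' @export
setMethod("accSignal", "MultiSensorRecording", function(x) x@acc)

#' @describeIn MultiSensorRecording-class the silhouette video stream.
#' @export
setMethod("videoStream", "MultiSensorRecording", function(x) x@video)

#' @describeIn MultiSensorRecording-class named sampling rates.
#' @export
setMethod("samplingRates", "MultiSensorRecording", function(x) x@rates)

#' @describeIn SubjectNormalizer-class the subject identifier.
#' @param x a `SubjectNormalizer`.
#' @export
setMethod("subjectId", "SubjectNormalizer", function(x) x@subjectId)

#' @describeIn SilhouetteVideo-class total number of frames.
#' @param x a `SilhouetteVideo`.
#' @export
setMethod("nFrames", "SilhouetteVideo", function(x) x@nFrames)

#' @describeIn SilhouetteVideo-class render frames `idx` as an
#'   `height x width x length(idx)` array.
#' @param idx integer frame indices (1-based).
#' @export
setMethod("getFrames", "SilhouetteVideo", function(x, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > x@nFrames))
    stop("frame index out of range [1, ", x@nFrames, "]")
  x@renderer(idx)
})

#' @describeIn FeatureSet-class the features-by-segments matrix.
#' @param x a `FeatureSet`.
#' @export
setMethod("featureMatrix", "FeatureSet", function(x)
  SummarizedExperiment::assay(x, "features"))

#' @describeIn FeatureSet-class the activity label of every column.
#' @export
setMethod("activityLabels", "FeatureSet", function(x)
  SummarizedExperiment::colData(x)$activity)

#' @describeIn FeatureSet-class the subject id of every column.
#' @export
setMethod("subjectIds", "FeatureSet", function(x)
  SummarizedExperiment::colData(x)$subject)

#' @describeIn FeatureSet-class the sensor name (emg/pressure/acc/video).
#' @export
setMethod("sensorId", "FeatureSet", function(x)
  S4Vectors::metadata(x)$sensor)

#' @describeIn RecognitionReport-class per-activity R/U statistics.
#' @param x a `RecognitionReport`.
#' @export
setMethod("activityStats", "RecognitionReport", function(x) x@perActivity)

#' @describeIn RecognitionReport-class per-subject R/U statistics.
#' @export
setMethod("subjectStats", "RecognitionReport", function(x) x@perSubject)

#' @describeIn RecognitionReport-class overall pooled statistics.
#' @export
setMethod("overallStats", "RecognitionReport", function(x) x@overall)

#' @describeIn RecognitionReport-class the sensor name.
#' @export
setMethod("sensorId", "RecognitionReport", function(x) x@sensor)

#' @describeIn ConfusionMatrix-class the percentage matrix.
#' @param x a `ConfusionMatrix`.
#' @export
setMethod("confusionPercent", "ConfusionMatrix", function(x) x@percent)

#' @describeIn ConfusionMatrix-class the underlying count matrix.
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) x@counts)

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSubjects, "subjects x",
      length(object@activities), "activities,",
      paste(object@repsRange, collapse = "-"), "repetitions each\n")
  cat("  rates: EMG", object@emgRate, "Hz | pressure", object@pressureRate,
      "Hz | acc", object@accRate, "Hz | video", object@videoRate, "fps (",
      paste(object@videoSize, collapse = "x"), "px )\n")
  cat("  noise sd:", paste(names(object@noiseSd), signif(object@noiseSd, 3),
                           sep = "=", collapse = ", "),
      "| subject scale sd:", object@subjectScaleSd,
      "| seed:", object@seed, "\n")
})

setMethod("show", "MultiSensorRecording", function(object) {
  span <- nrow(object@emg) / object@rates["emg"]
  cat("MultiSensorRecording for subject", object@subjectId, "\n")
  cat(sprintf("  span %.1f s (lead-in %.0f s)\n", span, object@leadIn))
  cat(sprintf("  emg %d x 8 @ %g Hz | pressure %d x 64 @ %g Hz | acc %d x 3 @ %g Hz\n",
              nrow(object@emg), object@rates["emg"],
              nrow(object@pressure), object@rates["pressure"],
              nrow(object@acc), object@rates["acc"]))
  cat(sprintf("  video %d frames %dx%d @ %g fps (lazy)\n",
              object@video@nFrames, object@video@width,
              object@video@height, object@video@fps))
})

setMethod("show", "SilhouetteVideo", function(object) {
  cat(sprintf("SilhouetteVideo: %d frames, %d x %d px @ %g fps\n",
              object@nFrames, object@width, object@height, object@fps))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet (%s, sensor %s): %d features x %d segments\n",
              sensorId(object), .sensorIds[[sensorId(object)]],
              nrow(object), ncol(object)))
  if (ncol(object) > 0L)
    cat("  subjects:", length(unique(subjectIds(object))),
        "| activities:", length(unique(activityLabels(object))), "\n")
})

setMethod("show", "RecognitionReport", function(object) {
  ov <- object@overall
  cat(sprintf("RecognitionReport (%s): R_all = %.1f%%, U_all = %.1f, U_act_all = %.1f\n",
              object@sensor, ov["R_all"], ov["U_all"], ov["U_act_all"]))
  cat(sprintf("  %d activities, %d subjects, %d test repetitions\n",
              nrow(object@perActivity), nrow(object@perSubject),
              as.integer(ov["W_all"])))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: %d classes, %d repetitions\n",
              nrow(object@percent), sum(object@counts)))
  print(round(object@percent, 1))
})
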
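#' @include classify.R evaluate.R biosignal.R video-features.R windowing.R
NULL

#' Build the feature set of one sensor over a whole cohort
#'
#' Cuts the fixed-width window of every segment from its subject's
#' recording, runs the sensor's feature chain ([buildBiosignalFeature()] or
#' [buildVideoFeature()]) and collects the vectors into a
#' [FeatureSet-class].
#'
#' @param recordings list of [MultiSensorRecording-class].
#' @param segments the cohort segment table.
#' @param sensor one of `"emg"`, `"pressure"`, `"acc"`, `"video"`.
#' @param spec a [windowSpec()].
#' @param flow a [flowParams()] (video only).
#' @param normalizers optional named list of [SubjectNormalizer-class]
#'   keyed by subject id; computed from the recordings when missing.
#' @return A [FeatureSet-class] with one column per segment, in segment
#'   table order.
#' @export
buildFeatureSet <- function(recordings, segments,
                            sensor = c("emg", "pressure", "acc", "video"),
                            spec = windowSpec(), flow = flowParams(),
                            normalizers = NULL) {
  sensor <- match.arg(sensor)
  .checkSegments(segments)
  names(recordings) <- vapply(recordings, subjectId, character(1L))
  if (sensor != "video" && is.null(normalizers))
    normalizers <- lapply(recordings, computeNormalizer)
  feats <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    rec <- recordings[[seg$subject]]
    if (is.null(rec)) stop("no recording for subject ", seg$subject)
    clip <- extractWindow(rec, seg, sensor, spec)
    if (sensor == "video") buildVideoFeature(clip, flow)
    else buildBiosignalFeature(clip, sensor,
                               normalizers[[seg$subject]])
  })
  FeatureSet(do.call(cbind, feats), subject = segments$subject,
             activity = segments$activity, sensor = sensor)
}

#' Run the full recognition pipeline on a synthetic cohort
#'
#' Convenience driver covering the whole analysis: simulate the cohort,
#' extract per-sensor feature sets, split the segments into stratified
#' learning and test sets (the same segment split for every sensor),
#' classify the test set with k-NN under the Manhattan metric, and compute
#' the recognition reports and confusion matrices.
#'
#' @param config a [CohortConfig-class].
#' @param sensors sensors to analyze (default all four).
#' @param spec a [windowSpec()].
#' @param flow a [flowParams()].
#' @param nTrain learning-set size; default half of the segments.
#' @param k neighbourhood size (default 1, the LOO-optimal value for this
#'   analysis); `k = "loo"` selects k by leave-one-out on the learning set.
#' @param kCandidates candidates for `k = "loo"`.
#' @param splitSeed seed of the train/test draw (default `seed + 1` of the
#'   config).
#' @return A list with `segments`, `features` (named list of
#'   [FeatureSet-class]), `trainIndex`, `predictions` (data.frame subject,
#'   activity, pred, sensor), `reports`, `confusions`, `accuracy` (named
#'   numeric, percent per sensor) and `k` (named, the k used per sensor).
#' @examples
#' \dontrun{
#' res <- runPipeline(cohortConfig(nSubjects = 4, repsRange = c(6, 6),
#'                                 videoSize = c(64, 48), seed = 1),
#'                    sensors = c("emg", "acc"))
#' res$accuracy
#' }
#' @export
runPipeline <- function(config, sensors = c("emg", "pressure", "acc",
                                            "video"),
                        spec = windowSpec(), flow = flowParams(),
                        nTrain = NULL, k = 1, kCandidates = c(1, 3, 5, 7),
                        splitSeed = NULL) {
  sensors <- match.arg(sensors, several.ok = TRUE)
  if (is.null(splitSeed)) splitSeed <- (config@seed + 1L) %% 2147483647L
  cohort <- generateCohort(config)
  segments <- cohort$segments
  if (is.null(nTrain)) nTrain <- floor(nrow(segments) / 2)

  normalizers <- lapply(cohort$recordings, computeNormalizer)
  names(normalizers) <- vapply(cohort$recordings, subjectId, character(1L))

  features <- lapply(sensors, function(s)
    buildFeatureSet(cohort$recordings, segments, s, spec, flow,
                    normalizers))
  names(features) <- sensors

  subjects <- sort(unique(segments$subject))
  predictions <- NULL
  reports <- confusions <- list()
  accuracy <- kUsed <- numeric(0)
  trainIndex <- NULL
  for (s in sensors) {
    split <- splitTrainTest(features[[s]], nTrain, seed = splitSeed)
    trainIndex <- split$trainIndex
    ks <- if (identical(k, "loo"))
      looSelectK(split$train, kCandidates)$bestK else k
    pred <- knnClassify(split$train, featureMatrix(split$test), k = ks)
    df <- data.frame(subject = subjectIds(split$test),
                     activity = activityLabels(split$test),
                     pred = pred, sensor = s)
    predictions <- rbind(predictions, df)
    reports[[s]] <- buildReport(df, sensor = s, subjects = subjects,
                                activities = intersect(activityLevels(),
                                                       segments$activity))
    confusions[[s]] <- buildConfusion(df$activity, df$pred,
                                      labels = sort(unique(
                                        segments$activity)))
    accuracy[s] <- overallStats(reports[[s]])[["R_all"]]
    kUsed[s] <- ks
  }
  list(segments = segments, features = features, trainIndex = trainIndex,
       predictions = predictions, reports = reports,
       confusions = confusions, accuracy = accuracy, k = kUsed)
}
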
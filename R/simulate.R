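#' @include AllClasses.R archetypes.R video-render.R
NULL

# Fixed per-subject seed offsets derived from the cohort seed, so each
# subject owns an independent, reproducible RNG substream.
.subjectSeed <- function(seed, i) (seed * 1009L + i * 7919L) %% 2147483647L

# Baseline standing plantar pressure per region (heel, center, front),
# replicated over the sensel layout.
.pressureBaseline <- function() {
  region <- c(0.60, 0.30, 0.45)[c(1L, 2L, 3L, 1L, 2L, 3L)]
  region[defaultPressureLayout()]
}

# Nominal sternum accelerometer offset (forward, lateral, vertical) around
# which per-subject offsets scatter; vertical carries the gravity component.
.accOffsetNominal <- c(0.30, -0.20, 1.00)

#' Generate a synthetic multi-sensor cohort
#'
#' Simulates, for every subject, a full recording session on all four
#' sensors plus the ground-truth segment table. Each subject performs a
#' randomized-order sequence of activity repetitions separated by rest gaps,
#' preceded by a stationary lead-in of at least 10 s. Each repetition is the
#' activity's sensor archetype ([activityArchetype()]), scaled by a
#' subject-specific log-normal amplitude multiplier, time-warped to a
#' duration drawn from the activity's log-normal duration model, plus
#' additive Gaussian noise. Video is exposed as a lazily rendered
#' [SilhouetteVideo-class] stream. Equal seeds give byte-identical output.
#'
#' @param config a [CohortConfig-class].
#' @return A list with components `recordings` (list of
#'   [MultiSensorRecording-class], one per subject) and `segments` (the
#'   segment table: data.frame with columns `subject`, `activity`,
#'   `t_start`, `t_end` in seconds).
#' @examples
#' cohort <- generateCohort(cohortConfig(nSubjects = 1, repsRange = c(2, 3),
#'                                       videoSize = c(64, 48), seed = 42))
#' head(cohort$segments)
#' cohort$recordings[[1]]
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  methods::validObject(config)
  recs <- vector("list", config@nSubjects)
  segs <- vector("list", config@nSubjects)
  for (i in seq_len(config@nSubjects)) {
    sid <- sprintf("S%02d", i)
    sim <- .simulateSubject(config, i, sid)
    recs[[i]] <- sim$recording
    segs[[i]] <- sim$segments
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  list(recordings = recs, segments = segments)
}

.simulateSubject <- function(config, i, sid) {
  seed <- .subjectSeed(config@seed, i)
  set.seed(seed)

  scales <- stats::setNames(exp(stats::rnorm(3) * config@subjectScaleSd),
                            c("emg", "pressure", "acc"))
  accOffset <- .accOffsetNominal + stats::rnorm(3) * 0.05

  acts <- config@activities
  pool <- seq(config@repsRange[1L], config@repsRange[2L])
  reps <- if (length(pool) == 1L) rep(pool, length(acts))
          else sample(pool, length(acts), replace = TRUE)
  activity <- rep(acts, times = reps)
  durations <- stats::rlnorm(length(activity),
                             meanlog = log(config@durationMedians[activity]),
                             sdlog = config@durationSdlog)
  durations <- pmin(pmax(durations, 0.6), 4.0)

  ord <- sample(length(activity))
  activity <- activity[ord]
  durations <- durations[ord]

  tStart <- config@leadIn + config@gap +
    cumsum(c(0, utils::head(durations + config@gap, -1L)))
  tEnd <- tStart + durations
  total <- tEnd[length(tEnd)] + config@tailPad
  segments <- data.frame(subject = sid, activity = activity,
                         t_start = tStart, t_end = tEnd)

  emg <- .renderBiosignal(segments, total, config@emgRate, "emg",
                          scales[["emg"]], config@noiseSd[["emg"]],
                          baseline = 0.02)
  pressure <- .renderBiosignal(segments, total, config@pressureRate,
                               "pressure", scales[["pressure"]],
                               config@noiseSd[["pressure"]],
                               baseline = .pressureBaseline() *
                                 scales[["pressure"]])
  acc <- .renderBiosignal(segments, total, config@accRate, "acc",
                          scales[["acc"]], config@noiseSd[["acc"]],
                          baseline = accOffset)

  video <- new("SilhouetteVideo",
               width = config@videoSize[1L], height = config@videoSize[2L],
               fps = config@videoRate,
               nFrames = as.integer(ceiling(total * config@videoRate)),
               renderer = .makeSessionRenderer(
                 config@videoSize[1L], config@videoSize[2L],
                 config@videoRate, segments, config@noiseSd[["video"]],
                 noiseSeedBase = seed))

  recording <- new("MultiSensorRecording", subjectId = sid,
                   emg = emg, pressure = pressure, acc = acc, video = video,
                   rates = c(emg = config@emgRate,
                             pressure = config@pressureRate,
                             acc = config@accRate,
                             video = config@videoRate),
                   leadIn = config@leadIn)
  list(recording = recording, segments = segments)
}

# Render one biosignal stream: baseline, plus the scaled, time-warped
# archetype inside every segment, plus white noise over the whole stream.
.renderBiosignal <- function(segments, total, rate, sensor, scale, noiseSd,
                             baseline) {
  n <- as.integer(ceiling(total * rate))
  nch <- c(emg = 8L, pressure = 64L, acc = 3L)[[sensor]]
  x <- matrix(rep(baseline, length.out = nch), nrow = n, ncol = nch,
              byrow = TRUE)
  t <- (seq_len(n) - 1L) / rate
  for (s in seq_len(nrow(segments))) {
    idx <- which(t >= segments$t_start[s] & t < segments$t_end[s])
    if (!length(idx)) next
    p <- (t[idx] - segments$t_start[s]) /
      (segments$t_end[s] - segments$t_start[s])
    arch <- activityArchetype(segments$activity[s], sensor)
    x[idx, ] <- x[idx, ] + scale * arch(p)
  }
  if (noiseSd > 0)
    x <- x + matrix(stats::rnorm(n * nch, sd = noiseSd), n, nch)
  colnames(x) <- switch(sensor,
                        emg = .emgChannels,
                        pressure = names(defaultPressureLayout()),
                        acc = .accChannels)
  x
}
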
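#' @include AllClasses.R archetypes.R
NULL

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. Used for per-frame video noise so that lazy frame
# rendering is deterministic regardless of rendering order.
.withLocalSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Oscillation geometry of the silhouette: period in seconds and amplitude in
# pixels (scaled to the frame so the peak speed stays near 2 px/frame at
# 25 fps for any frame size).
.oscPeriod <- 0.48
.oscAmplitude <- function(height) max(3, round(height / 16))

# Render one textured articulated silhouette frame. The body is a torso
# Gaussian plus a smaller leg Gaussian, carrying a sinusoidal texture fixed
# in body coordinates (so the pattern translates rigidly with the body).
# All terms are separable outer products for speed.
.renderFrame <- function(width, height, cx, cy, legDx = 0) {
  x <- seq_len(width)
  y <- seq_len(height)
  gx <- exp(-((x - cx) / (width * 0.07))^2)
  gy <- exp(-((y - cy) / (height * 0.18))^2)
  gxl <- exp(-((x - cx - legDx) / (width * 0.055))^2)
  gyl <- exp(-((y - cy - height * 0.22) / (height * 0.13))^2)
  body <- pmin(outer(gy, gx) + 0.8 * outer(gyl, gxl), 1)
  u <- x - cx
  v <- y - cy
  tex <- 0.55 +
    0.2 * outer(cos(2 * pi * v / 5.1), sin(2 * pi * u / 7.3)) +
    0.15 * (outer(cos(2 * pi * v / 11), sin(2 * pi * u / 11)) +
            outer(sin(2 * pi * v / 11), cos(2 * pi * u / 11)))
  0.08 + 0.85 * body * tex
}

# Silhouette center displacement at time t within a repetition: harmonic
# oscillation along the activity's first axis during the first half of the
# repetition and along its second axis during the second half. Display-space
# angles: x rightward, y upward on screen (so row displacement is -sin).
.segmentDisplacement <- function(t, tStart, tEnd, axes, amp) {
  p <- (t - tStart) / (tEnd - tStart)
  theta <- axes[[if (p < 0.5) 1L else 2L]] * pi / 180
  s <- amp * sin(2 * pi * (t - tStart) / .oscPeriod)
  c(dx = s * cos(theta), dy = -s * sin(theta))
}

# Build the lazy renderer closure for one subject's full session.
# schedule: data.frame(activity, t_start, t_end) sorted by t_start.
.makeSessionRenderer <- function(width, height, fps, schedule, noiseSd,
                                 noiseSeedBase) {
  cx0 <- width / 2
  cy0 <- height * 0.45
  amp <- .oscAmplitude(height)
  starts <- schedule$t_start
  ends <- schedule$t_end
  fams <- as.integer(substr(schedule$activity, 1L, 1L))
  axesList <- lapply(schedule$activity, videoTrajectory)
  function(idx) {
    out <- array(0, dim = c(height, width, length(idx)))
    for (k in seq_along(idx)) {
      t <- (idx[k] - 1) / fps
      seg <- findInterval(t, starts)
      cx <- cx0; cy <- cy0; legDx <- 0
      if (seg >= 1L && t < ends[seg]) {
        d <- .segmentDisplacement(t, starts[seg], ends[seg],
                                  axesList[[seg]], amp)
        cx <- cx0 + d[["dx"]]
        cy <- cy0 + d[["dy"]]
        if (fams[seg] == 6L) {
          p <- (t - starts[seg]) / (ends[seg] - starts[seg])
          legDx <- 3 * sin(2 * pi * p)
        }
      }
      fr <- .renderFrame(width, height, cx, cy, legDx)
      if (noiseSd > 0) {
        fr <- fr + .withLocalSeed(
          (noiseSeedBase + 131L * idx[k]) %% 2147483647L,
          matrix(stats::rnorm(height * width, sd = noiseSd), height, width))
      }
      out[, , k] <- pmin(pmax(fr, 0), 1)
    }
    out
  }
}

#' Render a silhouette video clip for one activity
#'
#' Synthesizes an ordered grayscale frame sequence showing a textured,
#' articulated body silhouette oscillating along the activity's motion axes
#' (see [videoTrajectory()]) over a static background. The special label
#' `"stand"` renders a motionless standing silhouette (all frames identical
#' when `noiseSd = 0`).
#'
#' @param activity an activity label, or `"stand"` for a static filler.
#' @param duration clip duration in seconds (> 0).
#' @param config a [CohortConfig-class]; supplies frame size and frame rate.
#' @param noiseSd additive pixel noise sd (default 0: noiseless frames).
#' @param noiseSeed base seed for the per-frame noise stream.
#' @return `height x width x round(duration * fps)` array of intensities in
#'   `[0, 1]`.
#' @examples
#' clip <- renderSilhouetteVideo("1a", 0.4, cohortConfig(videoSize = c(64, 48)))
#' dim(clip)
#' @export
renderSilhouetteVideo <- function(activity, duration, config = cohortConfig(),
                                  noiseSd = 0, noiseSeed = 1) {
  if (duration <= 0) stop("'duration' must be positive")
  fps <- config@videoRate
  n <- round(duration * fps)
  if (identical(activity, "stand")) {
    schedule <- data.frame(activity = "1a", t_start = duration + 1,
                           t_end = duration + 2)
  } else {
    .parseActivity(activity)
    schedule <- data.frame(activity = activity, t_start = 0,
                           t_end = duration)
  }
  renderer <- .makeSessionRenderer(config@videoSize[1L], config@videoSize[2L],
                                   fps, schedule, noiseSd, noiseSeed)
  renderer(seq_len(n))
}

#' Render a uniformly translating textured blob
#'
#' Produces a clip whose body silhouette translates rigidly at a constant,
#' known velocity: the ground truth for optical-flow recovery checks. The
#' per-frame displacement is stored in the `"displacement"` attribute.
#'
#' @param angleDeg motion direction in display-space degrees (0 = rightward,
#'   90 = upward on screen, counter-clockwise).
#' @param speed displacement magnitude in pixels/frame.
#' @param nFrames number of frames (>= 2).
#' @param width,height frame size in pixels.
#' @return `height x width x nFrames` array with attribute `displacement`,
#'   the `c(dx, dy)` column/row displacement per frame (dy positive
#'   downward, i.e. in row direction).
#' @examples
#' clip <- renderTranslationClip(0, speed = 1, nFrames = 3,
#'                               width = 64, height = 48)
#' attr(clip, "displacement")
#' @export
renderTranslationClip <- function(angleDeg, speed = 1.2, nFrames = 6,
                                  width = 180, height = 144) {
  stopifnot(nFrames >= 2, speed > 0)
  theta <- angleDeg * pi / 180
  dx <- speed * cos(theta)
  dy <- -speed * sin(theta)   # row direction is downward
  cx0 <- width / 2 - dx * (nFrames - 1) / 2
  cy0 <- height * 0.45 - dy * (nFrames - 1) / 2
  out <- array(0, dim = c(height, width, nFrames))
  for (k in seq_len(nFrames))
    out[, , k] <- pmin(.renderFrame(width, height,
                                    cx0 + dx * (k - 1), cy0 + dy * (k - 1)), 1)
  attr(out, "displacement") <- c(dx = dx, dy = dy)
  out
}
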